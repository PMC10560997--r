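#' Long-tailed phantom dataset specification
#'
#' Describes the class structure of a synthetic segmentation dataset:
#' a dominant background, one ellipse ("organ") per non-background class, and
#' optionally a set of rare tail classes rendered as 0-3 small blobs
#' ("lesions") per image, with per-class target pixel fractions enforced
#' pooled over the dataset rather than per image (a 1:1400 class cannot appear
#' in every small image).
#'
#' @param class_names character vector of class labels; index 1 (pixel value
#'   0) is the background.
#' @param target_ratios per-class target pixel fractions; strictly positive,
#'   summing to 1, background largest.
#' @param image_size `c(height, width)` in pixels.
#' @param intensity_model data frame with columns `class`, `mean`, `sd`
#'   (intensities in `[0,1]`), one row per class.
#' @param lesion_size_range `c(min, max)` equivalent blob diameter in pixels
#'   for tail classes; `min >= 1`, `max < min(image_size)`.
#' @param tail_classes names of classes rendered as small blobs; the
#'   remaining non-background classes are rendered as one ellipse per image.
#' @return An object of class `imbalance_spec`.
#' @seealso [phantom_preset()] for ready-made configurations.
#' @export
imbalance_spec <- function(class_names, target_ratios, image_size = c(64, 64),
                           intensity_model = NULL, lesion_size_range = c(3, 7),
                           tail_classes = character()) {
  C <- length(class_names)
  stopifnot(C >= 2, length(target_ratios) == C, length(image_size) == 2)
  if (any(target_ratios <= 0)) abort("`target_ratios` must be strictly positive")
  if (abs(sum(target_ratios) - 1) > 1e-8) abort("`target_ratios` must sum to 1")
  if (which.max(target_ratios) != 1) {
    abort("class 0 (background) must have the largest target ratio")
  }
  if (lesion_size_range[1] < 1 || lesion_size_range[2] >= min(image_size)) {
    abort("`lesion_size_range` must satisfy min >= 1 and max < min(image_size)")
  }
  if (lesion_size_range[1] > lesion_size_range[2]) {
    abort("`lesion_size_range` must be increasing")
  }
  if (!all(tail_classes %in% class_names[-1])) {
    abort("`tail_classes` must name non-background classes")
  }
  if (is.null(intensity_model)) {
    mu <- seq(0.2, 0.85, length.out = C)
    intensity_model <- tibble(class = class_names, mean = mu,
                              sd = rep(0.05, C))
  }
  stopifnot(all(c("class", "mean", "sd") %in% names(intensity_model)),
            nrow(intensity_model) == C,
            all(intensity_model$mean >= 0 & intensity_model$mean <= 1))
  structure(list(class_names = class_names,
                 target_ratios = as.numeric(target_ratios),
                 image_size = as.integer(image_size),
                 intensity_model = as_tibble(intensity_model),
                 lesion_size_range = as.numeric(lesion_size_range),
                 tail_classes = tail_classes),
            class = "imbalance_spec")
}

#' Ready-made phantom configurations
#'
#' * `"lits-like"` — background : organ : lesion pixel ratios 1 : 1/400 :
#'   1/1400 (liver-tumour style extreme tail).
#' * `"chaos-like"` — background plus four organs at 1/40, 1/200, 1/400 and
#'   1/400 of the background (multi-organ style).
#' * `"desk"` — background : organ : lesion at 1 : 1/9 : 1/100, a desk-scale
#'   long tail where the organ head class is large enough to learn from a few
#'   hundred 64 x 64 images while the lesion class stays rare.
#'
#' @param preset one of `"lits-like"`, `"chaos-like"`, `"desk"`.
#' @param image_size `c(height, width)`.
#' @return An [imbalance_spec].
#' @export
phantom_preset <- function(preset = c("desk", "lits-like", "chaos-like"),
                           image_size = c(64, 64)) {
  preset <- match.arg(preset)
  if (preset == "lits-like") {
    r <- c(1, 1 / 400, 1 / 1400)
    imbalance_spec(
      class_names = c("background", "organ", "lesion"),
      target_ratios = r / sum(r), image_size = image_size,
      intensity_model = tibble(class = c("background", "organ", "lesion"),
                               mean = c(0.20, 0.55, 0.85),
                               sd = c(0.05, 0.06, 0.05)),
      lesion_size_range = c(1, 3), tail_classes = "lesion")
  } else if (preset == "chaos-like") {
    r <- c(1, 1 / 40, 1 / 200, 1 / 400, 1 / 400)
    nm <- c("background", "liver", "spleen", "left_kidney", "right_kidney")
    imbalance_spec(
      class_names = nm, target_ratios = r / sum(r), image_size = image_size,
      intensity_model = tibble(class = nm,
                               mean = c(0.20, 0.45, 0.60, 0.75, 0.82),
                               sd = c(0.05, 0.06, 0.05, 0.05, 0.05)),
      lesion_size_range = c(2, 4))
  } else {
    r <- c(1, 1 / 9, 1 / 100)
    imbalance_spec(
      class_names = c("background", "organ", "lesion"),
      target_ratios = r / sum(r), image_size = image_size,
      intensity_model = tibble(class = c("background", "organ", "lesion"),
                               mean = c(0.20, 0.55, 0.85),
                               sd = c(0.05, 0.06, 0.05)),
      lesion_size_range = c(3, 7), tail_classes = "lesion")
  }
}

#' Domain-shift specification
#'
#' Parameterises an acquisition shift emulating a different patient population
#' or scanner: additive intensity offset, multiplicative contrast change about
#' mid-gray, stationary texture noise, and a resolution change (bilinear
#' down/up-sampling). The identity shift `(0, 1, 0, 1)` leaves data
#' bit-identical.
#'
#' @param intensity_offset additive shift in `[-1, 1]`.
#' @param contrast_scale multiplicative factor `> 0` applied about 0.5.
#' @param texture_noise_std standard deviation of added Gaussian noise.
#' @param resolution_factor relative resolution (`< 1` blurs via a down/up
#'   round trip, `1` leaves resolution untouched).
#' @return An object of class `shift_spec`.
#' @export
shift_spec <- function(intensity_offset = 0, contrast_scale = 1,
                       texture_noise_std = 0, resolution_factor = 1) {
  stopifnot(abs(intensity_offset) <= 1, contrast_scale > 0,
            texture_noise_std >= 0, resolution_factor > 0)
  structure(list(intensity_offset = intensity_offset,
                 contrast_scale = contrast_scale,
                 texture_noise_std = texture_noise_std,
                 resolution_factor = resolution_factor),
            class = "shift_spec")
}

#' Default out-of-distribution shift
#'
#' A moderate combined shift (brighter, higher contrast, added texture noise)
#' standing in for images from different equipment.
#' @return A [shift_spec].
#' @export
default_ood_shift <- function() {
  shift_spec(intensity_offset = 0.15, contrast_scale = 1.25,
             texture_noise_std = 0.05, resolution_factor = 1)
}

is_identity_shift <- function(shift) {
  shift$intensity_offset == 0 && shift$contrast_scale == 1 &&
    shift$texture_noise_std == 0 && shift$resolution_factor == 1
}

#' Construct an image sample
#'
#' @param image H x W (or H x W x 3) array of intensities in `[0,1]`.
#' @param mask H x W integer label matrix (segmentation) or `NULL`.
#' @param label integer class label (classification) or `NULL`.
#' @param sample_id character id.
#' @param domain_tag `"in_distribution"` or `"ood"`.
#' @return An object of class `image_sample`.
#' @export
image_sample <- function(image, mask = NULL, label = NULL, sample_id,
                         domain_tag = c("in_distribution", "ood")) {
  domain_tag <- match.arg(domain_tag)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(image)[1:2]), all(mask >= 0),
              all(mask == round(mask)))
  }
  structure(list(image = image, mask = mask, label = label,
                 sample_id = sample_id, domain_tag = domain_tag),
            class = "image_sample")
}

# low-frequency intensity field: coarse Gaussian grid, bilinear upsampled
lowfreq_field <- function(H, W, amp = 0.04, grid = 8) {
  g <- matrix(rnorm(grid * grid, 0, amp), grid, grid)
  bilinear_resize(g, H, W)
}

bilinear_resize <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  if (H == H2 && W == W2) return(m)
  ry <- (seq_len(H2) - 0.5) / H2 * H + 0.5
  rx <- (seq_len(W2) - 0.5) / W2 * W + 0.5
  y0 <- pmin(pmax(floor(ry), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(rx), 1), W); x1 <- pmin(x0 + 1, W)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y1, x0, drop = FALSE]
  c_ <- m[y0, x1, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  top <- a * (1 - wy) + b * wy
  bot <- c_ * (1 - wy) + d * wy
  top * rep(1 - wx, each = H2) + bot * rep(wx, each = H2)
}

# pixel set of an ellipse; returns logical H x W
ellipse_mask <- function(H, W, cy, cx, a, b, phi = 0) {
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(phi) * yy + sin(phi) * xx
  v <- -sin(phi) * yy + cos(phi) * xx
  (u / a)^2 + (v / b)^2 <= 1
}

# empirical mean rasterised pixel count of a blob of diameter d ~ U(range)
expected_blob_pixels <- function(range) {
  ds <- seq(range[1], range[2], length.out = 25)
  mean(vapply(ds, function(d) {
    r <- d / 2
    n <- ceiling(d) + 2
    cy <- n / 2 + 0.3; cx <- n / 2 + 0.3 # off-grid centre, typical case
    sum(ellipse_mask(n, n, cy, cx, r, r))
  }, numeric(1)))
}

# per-class per-image pixel budgets and blob rates; errors on infeasible specs
plan_geometry <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  hw <- H * W
  C <- length(spec$class_names)
  tail <- spec$class_names %in% spec$tail_classes
  blob_px <- expected_blob_pixels(spec$lesion_size_range)
  plan <- list()
  for (ci in seq_len(C)[-1]) {
    nm <- spec$class_names[ci]
    target <- spec$target_ratios[ci] * hw
    if (tail[ci]) {
      lambda <- target / blob_px
      if (lambda > 3) {
        abort(sprintf(
          paste0("infeasible spec: tail class '%s' needs %.2f blobs/image ",
                 "(max 3) at the requested ratio, image size and blob size"),
          nm, lambda))
      }
      plan[[nm]] <- list(kind = "blob", lambda = lambda, blob_px = blob_px)
    } else {
      if (target < 4) {
        abort(sprintf(
          "infeasible spec: organ class '%s' would occupy < 4 pixels per image",
          nm))
      }
      if (target > 0.5 * hw) {
        abort(sprintf("infeasible spec: organ class '%s' exceeds half the image", nm))
      }
      plan[[nm]] <- list(kind = "organ", area = target)
    }
  }
  plan
}

render_phantom <- function(spec, plan, phases, index) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  mask <- matrix(0L, H, W)
  C <- length(spec$class_names)
  organ_regions <- list()
  # organs: one ellipse per non-tail class, largest first
  organ_names <- names(plan)[vapply(plan, function(p) p$kind == "organ", logical(1))]
  organ_names <- organ_names[order(-vapply(organ_names, function(n) plan[[n]]$area, numeric(1)))]
  tail_names <- names(plan)[vapply(plan, function(p) p$kind == "blob", logical(1))]
  for (nm in organ_names) {
    ci <- match(nm, spec$class_names) - 1L
    A <- plan[[nm]]$area
    # compensate for tail blobs later carved out of this organ
    for (tn in tail_names) {
      p <- plan[[tn]]
      if (A >= 4 * p$blob_px) A <- A + p$lambda * p$blob_px
    }
    A <- A * runif(1, 0.85, 1.15)
    ar <- runif(1, 0.6, 1)
    a <- sqrt(A / (pi * ar)); b <- A / (pi * a)
    phi <- runif(1, 0, pi)
    r <- max(a, b)
    cy <- runif(1, min(r + 1, H / 2), max(H - r - 1, H / 2))
    cx <- runif(1, min(r + 1, W / 2), max(W - r - 1, W / 2))
    em <- ellipse_mask(H, W, cy, cx, a, b, phi)
    mask[em] <- ci
    organ_regions[[nm]] <- cbind(cy = cy, cx = cx, a = a, b = b, phi = phi)
  }
  # tail blobs: low-discrepancy per-image counts keep the pooled ratio on target
  for (nm in tail_names) {
    p <- plan[[nm]]
    ci <- match(nm, spec$class_names) - 1L
    u0 <- phases[[nm]]
    n_blob <- floor(p$lambda * index + u0) - floor(p$lambda * (index - 1) + u0)
    host <- if (length(organ_regions) > 0) organ_regions[[1]] else NULL
    use_host <- !is.null(host) &&
      pi * host[, "a"] * host[, "b"] >= 4 * p$blob_px
    for (j in seq_len(n_blob)) {
      d <- runif(1, spec$lesion_size_range[1], spec$lesion_size_range[2])
      a <- d / 2 * runif(1, 0.9, 1.1)
      b <- d / 2 * runif(1, 0.9, 1.1)
      if (use_host) {
        # rejection-free placement inside the host ellipse
        t <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1))
        u <- rad * cos(t) * host[, "a"] * 0.8
        v <- rad * sin(t) * host[, "b"] * 0.8
        cy <- host[, "cy"] + cos(host[, "phi"]) * u - sin(host[, "phi"]) * v
        cx <- host[, "cx"] + sin(host[, "phi"]) * u + cos(host[, "phi"]) * v
      } else {
        cy <- runif(1, 2, H - 2); cx <- runif(1, 2, W - 2)
      }
      cy <- min(max(cy, 1), H); cx <- min(max(cx, 1), W)
      mask[ellipse_mask(H, W, cy, cx, a, b)] <- ci
    }
  }
  # intensities: per-class Gaussian plus a shared low-frequency field
  img <- matrix(0, H, W)
  for (ci in seq_len(C) - 1L) {
    sel <- mask == ci
    if (!any(sel)) next
    im <- spec$intensity_model[ci + 1, ]
    img[sel] <- rnorm(sum(sel), im$mean, im$sd)
  }
  img <- img + lowfreq_field(H, W)
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, mask = mask)
}

#' Generate a seeded long-tailed segmentation phantom dataset
#'
#' Each image is rendered from a per-image random stream derived from
#' `(seed, image index)`, so a fixed seed yields a bit-identical dataset on
#' every call and extending `n_images` never reshuffles earlier images.
#' Pooled per-class pixel fractions converge to `spec$target_ratios`
#' (tail-class counts use a low-discrepancy per-image allocation so the
#' pooled ratio is on target even when most images carry no tail pixels).
#'
#' @param spec an [imbalance_spec].
#' @param n_images number of images (`>= 0`).
#' @param seed integer master seed.
#' @return A list of [image_sample] objects with class `phantom_dataset`;
#'   attributes carry the spec and seed.
#' @examples
#' ds <- generate_segmentation_dataset(phantom_preset("desk"), 10, seed = 7)
#' pooled_class_fractions(ds)
#' @export
generate_segmentation_dataset <- function(spec, n_images, seed = 0) {
  stopifnot(inherits(spec, "imbalance_spec"), n_images >= 0)
  plan <- plan_geometry(spec)
  tail_names <- names(plan)[vapply(plan, function(p) p$kind == "blob", logical(1))]
  phases <- with_stream(seed, "phase", 0,
                        setNames(as.list(runif(length(tail_names))), tail_names))
  samples <- lapply(seq_len(n_images), function(i) {
    ph <- with_stream(seed, "image", i, render_phantom(spec, plan, phases, i))
    image_sample(ph$image, mask = ph$mask,
                 sample_id = sprintf("seg_s%d_%05d", seed, i))
  })
  structure(samples, class = c("phantom_dataset", "list"),
            spec = spec, seed = seed, task = "segmentation")
}

#' Pooled per-class pixel fractions of a segmentation dataset
#'
#' @param samples list of [image_sample] objects with masks.
#' @param n_classes number of classes; inferred from the attached spec or the
#'   masks when omitted.
#' @return A tibble with `class`, `pixels` and `fraction`.
#' @export
pooled_class_fractions <- function(samples, n_classes = NULL) {
  spec <- attr(samples, "spec")
  if (is.null(n_classes)) {
    n_classes <- if (!is.null(spec)) length(spec$class_names) else
      max(vapply(samples, function(s) max(s$mask), numeric(1))) + 1
  }
  counts <- numeric(n_classes)
  for (s in samples) {
    t <- tabulate(s$mask + 1L, nbins = n_classes)
    counts <- counts + t
  }
  tibble(class = if (!is.null(spec)) spec$class_names else
           paste0("class_", seq_len(n_classes) - 1),
         pixels = counts, fraction = counts / sum(counts))
}

#' Generate an imbalanced binary classification phantom dataset
#'
#' Majority images are textured disks; minority images additionally carry a
#' faint concentric ring, a weak but learnable generative signature. With the
#' default counts `n_majority = 300`, `n_minority = 10` the class ratio is
#' exactly 1:30; the ratio is a free parameter rather than a fixed constant.
#'
#' @param n_majority,n_minority class sample counts (`>= 0`).
#' @param seed integer master seed.
#' @param image_size `c(height, width)`.
#' @return A `phantom_dataset` list of [image_sample] objects with `label`
#'   0 (majority) / 1 (minority). Emitted with a warning and a
#'   `degenerate_single_class` attribute when only one class is present.
#' @export
generate_classification_dataset <- function(n_majority = 300, n_minority = 10,
                                            seed = 0, image_size = c(32, 32)) {
  if (n_majority < 0 || n_minority < 0) abort("sample counts must be >= 0")
  H <- image_size[1]; W <- image_size[2]
  labels <- c(rep(0L, n_majority), rep(1L, n_minority))
  samples <- lapply(seq_along(labels), function(i) {
    img <- with_stream(seed, "cls_image", i, {
      base <- matrix(rnorm(H * W, 0.3, 0.05), H, W) + lowfreq_field(H, W, 0.06)
      cy <- runif(1, H * 0.35, H * 0.65); cx <- runif(1, W * 0.35, W * 0.65)
      r <- runif(1, min(H, W) * 0.2, min(H, W) * 0.33)
      disk <- ellipse_mask(H, W, cy, cx, r, r)
      base[disk] <- base[disk] + 0.3
      if (labels[i] == 1L) {
        yy <- matrix(seq_len(H), H, W) - cy
        xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
        rr <- sqrt(yy^2 + xx^2)
        ring <- abs(rr - 0.6 * r) < 1.2
        base[ring] <- base[ring] + 0.12
      }
      base[base < 0] <- 0; base[base > 1] <- 1
      base
    })
    image_sample(img, label = labels[i],
                 sample_id = sprintf("cls_s%d_%05d", seed, i))
  })
  out <- structure(samples, class = c("phantom_dataset", "list"),
                   seed = seed, task = "classification")
  if (length(unique(labels)) < 2 && length(labels) > 0) {
    warn("classification dataset contains a single class")
    attr(out, "degenerate_single_class") <- TRUE
  }
  out
}

#' Apply a domain shift to produce out-of-distribution samples
#'
#' Applies the acquisition shift in `shift` to every image, leaving masks and
#' labels untouched, and tags the outputs `"ood"`. Intensities falling outside
#' `[0,1]` are clipped and counted; a sample with more than 50% clipped pixels
#' triggers a warning. The identity shift returns the input unchanged (such
#' data is in-distribution by construction).
#'
#' @param samples non-empty list of [image_sample] objects.
#' @param shift a [shift_spec].
#' @param seed integer seed for the noise component.
#' @return The shifted samples; attribute `clipped_fraction` records the
#'   per-sample clipped-pixel fractions.
#' @export
apply_domain_shift <- function(samples, shift, seed = 0) {
  if (length(samples) == 0) abort("`samples` must be non-empty")
  stopifnot(inherits(shift, "shift_spec"))
  if (is_identity_shift(shift)) return(samples)
  clipped <- numeric(length(samples))
  out <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    img <- s$image
    d <- dim(img)
    img <- (img - 0.5) * shift$contrast_scale + 0.5 + shift$intensity_offset
    if (shift$texture_noise_std > 0) {
      img <- img + with_stream(seed, "shift_noise", i,
                               array(rnorm(length(img), 0, shift$texture_noise_std),
                                     dim = d))
    }
    if (shift$resolution_factor != 1) {
      f <- shift$resolution_factor
      H2 <- max(2, round(d[1] * f)); W2 <- max(2, round(d[2] * f))
      if (length(d) == 2) {
        img <- bilinear_resize(bilinear_resize(img, H2, W2), d[1], d[2])
      } else {
        for (c in seq_len(d[3])) {
          img[, , c] <- bilinear_resize(bilinear_resize(img[, , c], H2, W2),
                                        d[1], d[2])
        }
      }
    }
    nclip <- sum(img < 0 | img > 1)
    clipped[i] <<- nclip / length(img)
    if (clipped[i] > 0.5) {
      warn(sprintf("sample '%s': %.0f%% of pixels clipped by the domain shift",
                   s$sample_id, 100 * clipped[i]))
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    image_sample(img, mask = s$mask, label = s$label, sample_id = s$sample_id,
                 domain_tag = "ood")
  })
  attributes(out) <- attributes(samples)
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Manifest of a phantom dataset
#'
#' @param x a `phantom_dataset`.
#' @param ... unused.
#' @return A tibble with one row per sample: `sample_id`, `domain_tag`,
#'   `label` (classification) and image dimensions.
#' @export
as_tibble.phantom_dataset <- function(x, ...) {
  tibble(
    sample_id = vapply(x, function(s) s$sample_id, character(1)),
    domain_tag = vapply(x, function(s) s$domain_tag, character(1)),
    label = vapply(x, function(s) if (is.null(s$label)) NA_integer_ else s$label,
                   integer(1)),
    height = vapply(x, function(s) dim(s$image)[1], integer(1)),
    width = vapply(x, function(s) dim(s$image)[2], integer(1))
  )
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("<phantom_dataset>", length(x), "samples,",
      attr(x, "task") %||% "unknown", "task\n")
  invisible(x)
}
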