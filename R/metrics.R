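#' Pixel-level precision, recall and F1 for one class
#'
#' Counts pixel-level TP/FP/FN for `positive_class` between two integer
#' masks. Zero denominators yield a 0 with `degenerate = TRUE`; if the class
#' is absent from both masks all three metrics are undefined and flagged so
#' callers can exclude them from averages.
#'
#' @param pred_mask,true_mask integer matrices of identical shape.
#' @param positive_class integer class value scored as positive.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `tp`, `fp`, `fn`,
#'   `degenerate`, `undefined`.
#' @export
confusion_scores <- function(pred_mask, true_mask, positive_class) {
  stopifnot(all(dim(pred_mask) == dim(true_mask)))
  p <- pred_mask == positive_class
  t <- true_mask == positive_class
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  undefined <- !any(p) && !any(t)
  degenerate <- FALSE
  if (undefined) {
    precision <- recall <- f1 <- NA_real_
  } else {
    if (tp + fp == 0) { precision <- 0; degenerate <- TRUE } else precision <- tp / (tp + fp)
    if (tp + fn == 0) { recall <- 0; degenerate <- TRUE } else recall <- tp / (tp + fn)
    f1 <- if (precision + recall == 0) { degenerate <- TRUE; 0 } else {
      2 * precision * recall / (precision + recall)
    }
  }
  tibble(precision = precision, recall = recall, f1 = f1,
         tp = tp, fp = fp, fn = fn,
         degenerate = degenerate, undefined = undefined)
}

# boundary pixels of a binary mask under 4-connectivity (image border counts)
boundary_pixels <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[2:(H + 1), 2:(W + 1)] &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(m & !inner, arr.ind = TRUE)
}

#' Average symmetric surface distance (ASSD)
#'
#' The mean of the two directed mean nearest-surface distances between the
#' boundaries of two binary masks. Boundaries are pixels of the mask with at
#' least one 4-neighbour outside it (image borders count as outside).
#'
#' @param mask_a,mask_b logical/0-1 matrices of identical shape.
#' @param spacing pixel spacing `c(row, col)` (distances in mm when given in
#'   mm/pixel; defaults to 1 pixel).
#' @return Non-negative scalar; `Inf` with attribute `empty = TRUE` when
#'   either mask is empty.
#' @export
assd <- function(mask_a, mask_b, spacing = c(1, 1)) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  a <- boundary_pixels(mask_a > 0)
  b <- boundary_pixels(mask_b > 0)
  if (nrow(a) == 0 || nrow(b) == 0) {
    out <- Inf
    attr(out, "empty") <- TRUE
    return(out)
  }
  dy <- outer(a[, 1], b[, 1], "-") * spacing[1]
  dx <- outer(a[, 2], b[, 2], "-") * spacing[2]
  d <- sqrt(dy^2 + dx^2)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

#' Expected calibration error (ECE)
#'
#' Bins confidences into `n_bins` equal-width bins on (0, 1] and returns
#' \eqn{\sum_b \frac{n_b}{n} |acc(b) - conf(b)|}.
#'
#' @param confidences numeric vector in `[0, 1]`.
#' @param correctness logical (or 0/1) vector of the same length.
#' @param n_bins number of bins (default 10).
#' @return Scalar in `[0, 1]`.
#' @export
expected_calibration_error <- function(confidences, correctness, n_bins = 10) {
  if (length(confidences) == 0) abort("`confidences` must be non-empty")
  stopifnot(length(confidences) == length(correctness),
            all(confidences >= 0 & confidences <= 1))
  bin <- pmax(ceiling(confidences * n_bins), 1)
  n <- length(confidences)
  ece <- 0
  for (b in unique(bin)) {
    sel <- bin == b
    ece <- ece + sum(sel) / n * abs(mean(correctness[sel]) - mean(confidences[sel]))
  }
  ece
}

#' Negative log-likelihood of per-pixel predictions
#'
#' Mean \eqn{-\log p(\mathrm{true\ class})} with probabilities clamped at
#' `1e-12`. Identical by definition to [cce_loss()].
#'
#' @param prob_maps H x W x C probability array (or an n x C matrix for
#'   classification).
#' @param true_labels integer H x W mask (or length-n vector, 0-based).
#' @return Non-negative scalar.
#' @export
negative_log_likelihood <- function(prob_maps, true_labels) {
  if (is.matrix(prob_maps) && is.vector(true_labels)) {
    stopifnot(nrow(prob_maps) == length(true_labels))
    p_true <- prob_maps[cbind(seq_len(nrow(prob_maps)), true_labels + 1L)]
    return(mean(-log(pmax(p_true, 1e-12))))
  }
  stopifnot(all(dim(prob_maps)[1:2] == dim(true_labels)))
  as.numeric(cce_loss(prob_maps, true_labels))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted 1/2; computed from midranks.
#'
#' @param scores numeric vector.
#' @param binary_labels logical (or 0/1) vector, `TRUE`/1 = positive.
#' @return Scalar in `[0, 1]`.
#' @export
auroc <- function(scores, binary_labels) {
  y <- as.logical(binary_labels)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Two-sided paired t-test on metric scores
#'
#' @param scores_a,scores_b equal-length numeric vectors (`>= 2` pairs),
#'   e.g. per-fold metric values of two methods.
#' @return A one-row tibble: `t`, `p_value`, `mean_diff`, `degenerate`
#'   (`TRUE` when the differences have zero variance, in which case `t = 0`
#'   and `p_value = NA`).
#' @export
paired_t_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2)
  d <- scores_a - scores_b
  if (sd(d) == 0) {
    return(tibble(t = 0, p_value = NA_real_, mean_diff = mean(d),
                  degenerate = TRUE))
  }
  tt <- t.test(scores_a, scores_b, paired = TRUE)
  tibble(t = unname(tt$statistic), p_value = tt$p.value,
         mean_diff = mean(d), degenerate = FALSE)
}

#' Segmentation metric report for a dataset
#'
#' Computes per-foreground-class ASSD, precision, recall and F1, pixel-level
#' calibration (ECE over max-probability confidences) and NLL, using the
#' Monte-Carlo mean prediction. Per-class rows are macro-averaged into a
#' `"macro"` row (classes absent from both prediction and truth are excluded
#' from the average; empty-surface ASSDs are excluded likewise).
#'
#' @param fit a `begas_fit` (or an `hourglass_generator`).
#' @param samples list of masked [image_sample] objects.
#' @param cfg [dropout_config] controlling MC samples at evaluation.
#' @param n_bins ECE bin count.
#' @param spacing pixel spacing for ASSD.
#' @return A tibble of class `metric_report`: one row per class plus macro,
#'   with attribute `settings`.
#' @export
evaluate_model <- function(fit, samples, cfg = NULL, n_bins = 10,
                           spacing = c(1, 1)) {
  gen <- if (inherits(fit, "begas_fit")) fit$generator else fit
  cfg <- cfg %||% (if (inherits(fit, "begas_fit")) fit$cfg$dropout else dropout_config())
  C <- gen$spec$n_classes
  class_names <- if (inherits(fit, "begas_fit") && !is.null(fit$class_names)) {
    fit$class_names
  } else paste0("class_", seq_len(C) - 1)
  per_class <- vector("list", length(samples))
  conf_all <- list(); corr_all <- list(); nll_all <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    maps <- mc_predict(gen, s$image, cfg)
    m <- predictive_mean(maps)
    pred <- apply(m, c(1, 2), which.max) - 1L
    rows <- lapply(seq_len(C - 1), function(ci) {
      cs <- confusion_scores(pred, s$mask, ci)
      sa <- assd(pred == ci, s$mask == ci, spacing)
      cs$assd <- as.numeric(sa)
      cs$class <- class_names[ci + 1]
      cs
    })
    per_class[[i]] <- dplyr::bind_rows(rows)
    conf_all[[i]] <- as.vector(apply(m, c(1, 2), max))
    corr_all[[i]] <- as.vector(pred == s$mask)
    nll_all[i] <- negative_log_likelihood(m, s$mask)
  }
  ece <- expected_calibration_error(unlist(conf_all), unlist(corr_all), n_bins)
  nll <- mean(nll_all)
  all_rows <- dplyr::bind_rows(per_class)
  by_class <- all_rows |>
    dplyr::filter(!.data$undefined) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      precision = mean(.data$precision), recall = mean(.data$recall),
      f1 = mean(.data$f1),
      assd = mean(.data$assd[is.finite(.data$assd)]),
      n_images = dplyr::n(), .groups = "drop")
  macro <- tibble(class = "macro",
                  precision = mean(by_class$precision),
                  recall = mean(by_class$recall),
                  f1 = mean(by_class$f1),
                  assd = mean(by_class$assd[is.finite(by_class$assd)]),
                  n_images = length(samples))
  rep <- dplyr::bind_rows(by_class, macro)
  rep$ece <- ece
  rep$nll <- nll
  structure(rep, class = c("metric_report", class(rep)),
            settings = list(n_mc = cfg$n_samples, sigma = cfg$sigma,
                            n_bins = n_bins, spacing = spacing,
                            averaging = "macro over foreground classes"))
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> settings:",
      paste(names(attr(x, "settings")), unlist(lapply(attr(x, "settings"), paste, collapse = "x")),
            sep = "=", collapse = ", "), "\n")
  NextMethod()
}
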