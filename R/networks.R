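#' Network parameter container
#'
#' Holds the ordered per-layer parameter arrays \eqn{\theta = \{\theta_1, \dots,
#' \theta_d\}} of a network. Each conv layer contributes a weight matrix
#' (`<layer>.W`, laid out `k*k*C_in` by `C_out`) and a bias vector (`<layer>.b`).
#'
#' @param theta named list of finite numeric arrays.
#' @return An object of class `network_parameters` with attribute `d`, the
#'   number of layers.
#' @export
network_parameters <- function(theta) {
  stopifnot(is.list(theta), length(theta) >= 1, !is.null(names(theta)))
  ok <- vapply(theta, function(a) is.numeric(a) && all(is.finite(a)), logical(1))
  if (!all(ok)) {
    abort(paste0("non-finite parameters in layer(s): ",
                 paste(names(theta)[!ok], collapse = ", ")))
  }
  d <- sum(grepl("\\.W$", names(theta)))
  if (d < 1) abort("at least one weight layer ('<name>.W') is required")
  structure(list(theta = theta, d = d), class = "network_parameters")
}

#' @export
print.network_parameters <- function(x, ...) {
  n <- sum(vapply(x$theta, length, integer(1)))
  cat("<network_parameters>", x$d, "layers,", n, "parameters\n")
  invisible(x)
}

#' Monte-Carlo dropout configuration
#'
#' Configures the multiplicative Gaussian weight noise \eqn{\delta \sim
#' N(1, \sigma^2)} used to draw an ensemble of `n_samples` network
#' configurations \eqn{\hat\theta_i = \theta \cdot \delta_i}. `schedule`
#' makes \eqn{\sigma} dynamic over training: `"constant"` keeps it fixed,
#' `"linear_decay"` shrinks it linearly to `sigma_final` over the run.
#'
#' @param sigma standard deviation of the weight noise, `>= 0` (0 disables it).
#' @param n_samples number of Monte-Carlo configurations N, `>= 1`.
#' @param seed integer seed for the noise stream.
#' @param schedule `"constant"` or `"linear_decay"`.
#' @param sigma_final final sigma for `"linear_decay"`.
#' @return An object of class `dropout_config`.
#' @export
dropout_config <- function(sigma = 0.1, n_samples = 5, seed = 0,
                           schedule = c("constant", "linear_decay"),
                           sigma_final = 0) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    abort("`sigma` must be a single number >= 0")
  }
  if (!is.numeric(n_samples) || n_samples < 1) abort("`n_samples` must be >= 1")
  schedule <- match.arg(schedule)
  structure(list(sigma = sigma, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), schedule = schedule,
                 sigma_final = sigma_final),
            class = "dropout_config")
}

# sigma at a training progress fraction in [0, 1]
sigma_at <- function(cfg, progress = 0) {
  if (cfg$schedule == "constant") return(cfg$sigma)
  cfg$sigma + (cfg$sigma_final - cfg$sigma) * progress
}

#' Draw one perturbed network configuration
#'
#' Returns \eqn{\hat\theta = \theta \odot \delta} with \eqn{\delta} drawn
#' elementwise from \eqn{N(1, \sigma^2)}. The draw is a pure function of
#' `(cfg$seed, draw_index)`: member `i` of the ensemble is the same arrays
#' no matter how many other members are materialised, and the input
#' parameters are never modified.
#'
#' @param params a [network_parameters] object.
#' @param cfg a [dropout_config].
#' @param draw_index member index in `[0, cfg$n_samples)`.
#' @param sigma optional override of `cfg$sigma` (used by sigma schedules).
#' @return A new [network_parameters] object.
#' @export
sample_configuration <- function(params, cfg, draw_index = 0, sigma = NULL) {
  stopifnot(inherits(params, "network_parameters"), inherits(cfg, "dropout_config"))
  if (draw_index < 0 || draw_index >= cfg$n_samples) {
    abort("`draw_index` must lie in [0, n_samples)")
  }
  s <- sigma %||% cfg$sigma
  if (s < 0) abort("`sigma` must be >= 0")
  if (s == 0) return(params)
  theta <- with_stream(cfg$seed, "dropout", draw_index, {
    lapply(params$theta, function(a) a * array(rnorm(length(a), 1, s), dim = dim(a) %||% length(a)))
  })
  network_parameters(theta)
}

#' Materialise a configuration ensemble
#'
#' @param params a [network_parameters] object.
#' @param cfg a [dropout_config]; `cfg$n_samples` members are drawn.
#' @return An object of class `configuration_ensemble` with a `members` list.
#' @export
configuration_ensemble <- function(params, cfg) {
  members <- lapply(seq_len(cfg$n_samples) - 1L,
                    function(i) sample_configuration(params, cfg, i))
  structure(list(members = members, cfg = cfg), class = "configuration_ensemble")
}

#' Generator architecture specification
#'
#' A stacked hourglass segmentation generator: a stem convolution, `stacks`
#' hourglass stages (three 2x downsamplings to an 8x-coarser bottleneck,
#' symmetric nearest-neighbour upsampling with skip connections), and a 1x1
#' classification head with per-pixel softmax. The random vector `z` is
#' broadcast and concatenated to the bottleneck features of every stage, so
#' the mapping is `(z, x) -> per-pixel class probabilities`.
#'
#' @param n_classes number of segmentation classes C (`>= 2`).
#' @param stacks number of hourglass stages (`>= 1`).
#' @param base_channels feature width of every conv layer.
#' @param input_channels image channels (1 grayscale, 3 RGB).
#' @param noise_dim length of the random vector z.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_classes, stacks = 2, base_channels = 8,
                           input_channels = 1, noise_dim = 16) {
  stopifnot(n_classes >= 2, stacks >= 1, base_channels >= 1,
            input_channels >= 1, noise_dim >= 1)
  structure(list(n_classes = as.integer(n_classes), stacks = as.integer(stacks),
                 base_channels = as.integer(base_channels),
                 input_channels = as.integer(input_channels),
                 noise_dim = as.integer(noise_dim), depth = 3L),
            class = "generator_spec")
}

#' Markovian (patch) discriminator specification
#'
#' The discriminator scores local patches of an (image, label-map) pair rather
#' than the whole image: strided pooling stages shrink the map so that each
#' output unit sees roughly `patch_receptive_field` pixels, and a sigmoid head
#' emits one realness score per patch.
#'
#' @param patch_receptive_field approximate patch size in pixels (`>= 4`).
#' @param base_channels feature width.
#' @param loss_type auxiliary segmentation loss this discriminator is paired
#'   with in the ensemble objective: `"mae"`, `"cce"` or `"dice"`.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(patch_receptive_field = 16, base_channels = 8,
                               loss_type = c("mae", "cce", "dice")) {
  stopifnot(patch_receptive_field >= 4)
  loss_type <- match.arg(loss_type)
  structure(list(patch_receptive_field = as.integer(patch_receptive_field),
                 base_channels = as.integer(base_channels),
                 loss_type = loss_type,
                 n_pools = max(1L, as.integer(round(log2(patch_receptive_field)) - 2L))),
            class = "discriminator_spec")
}

gen_layer_names <- function(spec) {
  nm <- c("stem")
  for (s in seq_len(spec$stacks)) {
    nm <- c(nm, paste0("s", s, ".", c("enc1", "enc2", "enc3", "bott",
                                      "dec3", "dec2", "dec1")))
  }
  c(nm, "head")
}

gen_layer_shapes <- function(spec) {
  f <- spec$base_channels
  shapes <- list(stem = c(3, spec$input_channels, f))
  for (s in seq_len(spec$stacks)) {
    p <- paste0("s", s, ".")
    shapes[[paste0(p, "enc1")]] <- c(3, f, f)
    shapes[[paste0(p, "enc2")]] <- c(3, f, f)
    shapes[[paste0(p, "enc3")]] <- c(3, f, f)
    shapes[[paste0(p, "bott")]] <- c(3, f + spec$noise_dim, f)
    shapes[[paste0(p, "dec3")]] <- c(3, f, f)
    shapes[[paste0(p, "dec2")]] <- c(3, f, f)
    shapes[[paste0(p, "dec1")]] <- c(3, f, f)
  }
  # the raw image is concatenated onto the head input (input skip): the
  # normalised feature path alone is blind to global intensity statistics
  shapes[["head"]] <- c(1, f + spec$input_channels, spec$n_classes)
  shapes
}

init_params <- function(shapes, init = c("gaussian", "he"), sd = 0.001, seed = 0,
                        norm_layers = character()) {
  init <- match.arg(init)
  theta <- with_stream(seed, "init", 0, {
    th <- list()
    for (nm in names(shapes)) {
      sh <- shapes[[nm]] # (k, cin, cout)
      fan_in <- sh[1] * sh[1] * sh[2]
      s <- if (init == "gaussian") sd else sqrt(2 / fan_in)
      th[[paste0(nm, ".W")]] <- matrix(rnorm(fan_in * sh[3], 0, s), fan_in, sh[3])
      th[[paste0(nm, ".b")]] <- numeric(sh[3])
      if (nm %in% norm_layers) {
        th[[paste0(nm, ".gamma")]] <- rep(1, sh[3])
        th[[paste0(nm, ".beta")]] <- numeric(sh[3])
      }
    }
    th
  })
  network_parameters(theta)
}

# conv (+ instance norm) + leaky-ReLU block
block_fw <- function(x, th, nm, k, norm = TRUE) {
  a <- conv_fw(x, th[[paste0(nm, ".W")]], th[[paste0(nm, ".b")]], k)
  if (norm) {
    nc <- instnorm_fw(a, th[[paste0(nm, ".gamma")]], th[[paste0(nm, ".beta")]])
    pre <- nc$y
  } else {
    nc <- NULL
    pre <- a
  }
  list(y = relu(pre), cache = list(x = x, pre = pre, nc = nc))
}

block_bw <- function(th, nm, cache, gy, k, norm = TRUE, g) {
  gr <- relu_bw(cache$pre, gy)
  if (norm) {
    nb <- instnorm_bw(cache$nc, th[[paste0(nm, ".gamma")]], gr)
    g[[paste0(nm, ".gamma")]] <- nb$dgamma
    g[[paste0(nm, ".beta")]] <- nb$dbeta
    gr <- nb$gx
  }
  cb <- conv_bw(cache$x, th[[paste0(nm, ".W")]], gr, k)
  g[[paste0(nm, ".W")]] <- cb$gW
  g[[paste0(nm, ".b")]] <- cb$gb
  list(gx = cb$gx, g = g)
}

#' Build a stacked hourglass generator
#'
#' Weights are initialised from a zero-mean Gaussian with standard deviation
#' 0.001 and biases at zero; the initial output is therefore an almost-uniform
#' softmax at every pixel.
#'
#' @param spec a [generator_spec].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `hourglass_generator` with elements `spec` and
#'   `params` (a [network_parameters]).
#' @export
build_generator <- function(spec, seed = 0) {
  stopifnot(inherits(spec, "generator_spec"))
  shapes <- gen_layer_shapes(spec)
  params <- init_params(shapes, "gaussian", sd = 0.001, seed = seed,
                        norm_layers = setdiff(names(shapes), "head"))
  structure(list(spec = spec, params = params, kernel = 3L),
            class = "hourglass_generator")
}

#' Build a patch discriminator
#'
#' The discriminator conditions on the label map: its input is the image
#' concatenated channelwise with the (one-hot or predicted soft) class map.
#' Weights use He initialisation (random; no pretraining).
#'
#' @param spec a [discriminator_spec].
#' @param image_channels image channels of the conditioned input.
#' @param n_classes number of classes in the label map.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `patch_discriminator`.
#' @export
build_discriminator <- function(spec, image_channels = 1, n_classes = 2, seed = 0) {
  stopifnot(inherits(spec, "discriminator_spec"))
  f <- spec$base_channels
  cin <- image_channels + n_classes
  shapes <- list()
  for (i in seq_len(spec$n_pools)) {
    shapes[[paste0("c", i)]] <- c(3, if (i == 1) cin else f, f)
  }
  shapes[["mid"]] <- c(3, f, f)
  shapes[["head"]] <- c(1, f, 1)
  # no norm on the first conv (standard patch-discriminator practice)
  params <- init_params(shapes, "he", seed = seed,
                        norm_layers = setdiff(names(shapes), c("c1", "head")))
  structure(list(spec = spec, params = params,
                 image_channels = as.integer(image_channels),
                 n_classes = as.integer(n_classes)),
            class = "patch_discriminator")
}

check_div <- function(H, W, factor) {
  if (H %% factor != 0 || W %% factor != 0) {
    abort(sprintf(
      "input size %dx%d is not divisible by the network downsampling factor %d",
      H, W, factor))
  }
}

# Forward pass of the hourglass generator. Returns probs (+ cache for backprop).
gen_forward <- function(spec, theta, x, z, want_cache = FALSE) {
  x <- as_chw(x)
  H <- dim(x)[1]; W <- dim(x)[2]
  check_div(H, W, 8L)
  if (dim(x)[3] != spec$input_channels) abort("wrong number of image channels")
  if (length(z) != spec$noise_dim) abort("z has wrong length")
  th <- theta$theta
  cache <- list()
  stem <- block_fw(x, th, "stem", 3)
  h <- stem$y
  cache$stem <- stem$cache
  stacks <- vector("list", spec$stacks)
  for (s in seq_len(spec$stacks)) {
    p <- paste0("s", s, ".")
    st <- list()
    e1 <- block_fw(h, th, paste0(p, "enc1"), 3); st$e1 <- e1$cache
    st$p1 <- pool_fw(e1$y)
    e2 <- block_fw(st$p1$y, th, paste0(p, "enc2"), 3); st$e2 <- e2$cache
    st$p2 <- pool_fw(e2$y)
    e3 <- block_fw(st$p2$y, th, paste0(p, "enc3"), 3); st$e3 <- e3$cache
    st$p3 <- pool_fw(e3$y)
    hb <- dim(st$p3$y)[1]; wb <- dim(st$p3$y)[2]
    zb <- array(rep(z, each = hb * wb), dim = c(hb, wb, spec$noise_dim))
    bcat <- concat3(st$p3$y, zb)
    bo <- block_fw(bcat, th, paste0(p, "bott"), 3); st$bo <- bo$cache
    u3 <- up2(bo$y)
    d3b <- block_fw(u3, th, paste0(p, "dec3"), 3); st$d3 <- d3b$cache
    d3 <- d3b$y + e3$y
    u2 <- up2(d3)
    d2b <- block_fw(u2, th, paste0(p, "dec2"), 3); st$d2 <- d2b$cache
    d2 <- d2b$y + e2$y
    u1 <- up2(d2)
    d1b <- block_fw(u1, th, paste0(p, "dec1"), 3); st$d1 <- d1b$cache
    h <- d1b$y + e1$y
    st$edims <- list(d1 = dim(e1$y), d2 = dim(e2$y), d3 = dim(e3$y))
    stacks[[s]] <- st
  }
  cache$stacks <- stacks
  cache$h_final <- concat3(h, x)
  logits <- conv_fw(cache$h_final, th[["head.W"]], th[["head.b"]], 1)
  probs <- softmax3(logits)
  if (any(!is.finite(probs))) abort("non-finite generator output")
  out <- list(probs = probs, logits = logits)
  if (want_cache) out$cache <- cache
  out
}

# Backward pass; gLogits is the loss gradient wrt the pre-softmax logits.
gen_backward <- function(spec, theta, cache, gLogits) {
  th <- theta$theta
  g <- list()
  bh <- conv_bw(cache$h_final, th[["head.W"]], gLogits, 1)
  g[["head.W"]] <- bh$gW; g[["head.b"]] <- bh$gb
  f <- spec$base_channels
  gh <- bh$gx[, , seq_len(f), drop = FALSE] # image channels carry no gradient
  for (s in rev(seq_len(spec$stacks))) {
    p <- paste0("s", s, ".")
    st <- cache$stacks[[s]]
    b1 <- block_bw(th, paste0(p, "dec1"), st$d1, gh, 3, TRUE, g)
    g <- b1$g; gskip1 <- gh
    gd2 <- up2_bw(b1$gx)
    b2 <- block_bw(th, paste0(p, "dec2"), st$d2, gd2, 3, TRUE, g)
    g <- b2$g; gskip2 <- gd2
    gd3 <- up2_bw(b2$gx)
    b3 <- block_bw(th, paste0(p, "dec3"), st$d3, gd3, 3, TRUE, g)
    g <- b3$g; gskip3 <- gd3
    grb <- up2_bw(b3$gx)
    bb <- block_bw(th, paste0(p, "bott"), st$bo, grb, 3, TRUE, g)
    g <- bb$g
    gp3 <- bb$gx[, , seq_len(f), drop = FALSE]
    gr3 <- pool_bw(st$p3$idx, gp3, st$edims$d3[1], st$edims$d3[2]) + gskip3
    be3 <- block_bw(th, paste0(p, "enc3"), st$e3, gr3, 3, TRUE, g)
    g <- be3$g
    gr2 <- pool_bw(st$p2$idx, be3$gx, st$edims$d2[1], st$edims$d2[2]) + gskip2
    be2 <- block_bw(th, paste0(p, "enc2"), st$e2, gr2, 3, TRUE, g)
    g <- be2$g
    gr1 <- pool_bw(st$p1$idx, be2$gx, st$edims$d1[1], st$edims$d1[2]) + gskip1
    be1 <- block_bw(th, paste0(p, "enc1"), st$e1, gr1, 3, TRUE, g)
    g <- be1$g
    gh <- be1$gx
  }
  bs <- block_bw(th, "stem", cache$stem, gh, 3, TRUE, g)
  bs$g
}

# Forward pass of the patch discriminator on (image, class-map) input.
disc_forward <- function(disc, theta, x, y_probs, want_cache = FALSE) {
  x <- as_chw(x); y_probs <- as_chw(y_probs)
  if (!all(dim(x)[1:2] == dim(y_probs)[1:2])) {
    abort("image and label map have mismatched spatial dimensions")
  }
  if (dim(y_probs)[3] != disc$n_classes) abort("label map has wrong class count")
  np <- disc$spec$n_pools
  check_div(dim(x)[1], dim(x)[2], 2L^np)
  th <- theta$theta
  h <- concat3(x, y_probs)
  cache <- list(convs = vector("list", np))
  for (i in seq_len(np)) {
    blk <- block_fw(h, th, paste0("c", i), 3, norm = (i > 1))
    pl <- pool_fw(blk$y)
    cache$convs[[i]] <- list(blk = blk$cache, rdim = dim(blk$y), pool = pl)
    h <- pl$y
  }
  mid <- block_fw(h, th, "mid", 3)
  cache$mid <- mid$cache
  cache$rm <- mid$y
  logits <- conv_fw(mid$y, th[["head.W"]], th[["head.b"]], 1)[, , 1]
  scores <- sigmoid(logits)
  out <- list(scores = scores, logits = logits)
  if (want_cache) out$cache <- cache
  out
}

# Backward; gLogits has the score-grid shape. Returns grads and the gradient
# wrt the input block (image channels first, then class-map channels).
disc_backward <- function(disc, theta, cache, gLogits) {
  th <- theta$theta
  g <- list()
  d <- dim(cache$rm)
  gl <- array(gLogits, dim = c(d[1], d[2], 1))
  bh <- conv_bw(cache$rm, th[["head.W"]], gl, 1)
  g[["head.W"]] <- bh$gW; g[["head.b"]] <- bh$gb
  bm <- block_bw(th, "mid", cache$mid, bh$gx, 3, TRUE, g)
  g <- bm$g
  gh <- bm$gx
  for (i in rev(seq_len(disc$spec$n_pools))) {
    cv <- cache$convs[[i]]
    gr <- pool_bw(cv$pool$idx, gh, cv$rdim[1], cv$rdim[2])
    bc <- block_bw(th, paste0("c", i), cv$blk, gr, 3, norm = (i > 1), g)
    g <- bc$g
    gh <- bc$gx
  }
  list(grads = g, gx_input = gh)
}

#' Predict per-pixel class probabilities with a generator
#'
#' @param object an `hourglass_generator`.
#' @param x image (H x W or H x W x channels array, intensities in `[0,1]`).
#' @param z random vector of length `noise_dim`; drawn from `N(0,1)` under
#'   `seed` when omitted.
#' @param theta optional parameter override (e.g. a perturbed configuration).
#' @param seed seed used when `z` is omitted.
#' @param ... unused.
#' @return H x W x C array of per-pixel class probabilities.
#' @export
predict.hourglass_generator <- function(object, x, z = NULL, theta = NULL,
                                        seed = 0, ...) {
  if (is.null(z)) z <- with_stream(seed, "z", 0, rnorm(object$spec$noise_dim))
  gen_forward(object$spec, theta %||% object$params, x, z)$probs
}

#' Score an (image, label map) pair with a patch discriminator
#'
#' @param object a `patch_discriminator`.
#' @param x image array.
#' @param y_probs one-hot or soft class map, H x W x C.
#' @param theta optional parameter override.
#' @param ... unused.
#' @return Matrix of patch realness scores in (0, 1).
#' @export
predict.patch_discriminator <- function(object, x, y_probs, theta = NULL, ...) {
  disc_forward(object, theta %||% object$params, x, y_probs)$scores
}
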