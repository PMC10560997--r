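#' Normalized class-frequency specification
#'
#' The class frequencies \eqn{\tau} of the training split enter the second
#' moment as a rarity-dependent offset `diag(1/tau)`: rare classes receive a
#' larger baseline uncertainty. `tau_mode = "vector"` (default) reads
#' \eqn{\tau^{-1} I_C} with the per-class frequencies on the diagonal;
#' `"scalar"` reads \eqn{\tau} as a single model precision (the mean
#' frequency), giving a constant diagonal offset.
#'
#' @param tau strictly positive length-C vector of normalized class
#'   frequencies (sums to 1).
#' @param tau_mode `"vector"` or `"scalar"`.
#' @return An object of class `class_frequency_spec`.
#' @export
class_frequency_spec <- function(tau, tau_mode = c("vector", "scalar")) {
  tau_mode <- match.arg(tau_mode)
  if (any(tau <= 0)) abort("`tau` must be strictly positive (zero frequency divides by zero)")
  if (abs(sum(tau) - 1) > 1e-6) abort("`tau` must sum to 1")
  structure(list(tau = as.numeric(tau), C = length(tau), tau_mode = tau_mode),
            class = "class_frequency_spec")
}

tau_inverse_diag <- function(freq) {
  if (freq$tau_mode == "vector") 1 / freq$tau else rep(1 / mean(freq$tau), freq$C)
}

#' Class frequencies of a training split
#'
#' Computes \eqn{\tau} from the pooled pixel counts of the whole split (not
#' per batch), which keeps the offset stable.
#'
#' @param samples segmentation `phantom_dataset` (or list of masked samples).
#' @param n_classes number of classes.
#' @param tau_mode passed to [class_frequency_spec()].
#' @return A [class_frequency_spec].
#' @export
class_frequencies <- function(samples, n_classes = NULL, tau_mode = "vector") {
  fr <- pooled_class_fractions(samples, n_classes)
  tau <- fr$fraction
  if (any(tau == 0)) {
    # a class absent from the split still needs a finite frequency
    tau <- (fr$pixels + 1) / sum(fr$pixels + 1)
  }
  class_frequency_spec(tau, tau_mode)
}

#' Monte-Carlo prediction with a configuration ensemble
#'
#' Runs `cfg$n_samples` stochastic forward passes, one per perturbed
#' configuration \eqn{\hat\theta_i = \theta \cdot \delta_i}, and returns the
#' per-member probability maps. By default the random vector `z` is drawn once
#' and held fixed across members so that the spread across members isolates
#' the weight-noise (epistemic) component; set `resample_z = TRUE` to draw a
#' fresh `z` per member.
#'
#' @param generator an `hourglass_generator`.
#' @param params base [network_parameters] (defaults to the generator's own).
#' @param x input image.
#' @param cfg a [dropout_config]; `cfg$seed` drives both the weight noise and z.
#' @param resample_z draw a new z per member?
#' @return A list of `n_samples` H x W x C probability arrays.
#' @export
mc_predict <- function(generator, x, cfg, params = NULL, resample_z = FALSE) {
  stopifnot(inherits(generator, "hourglass_generator"),
            inherits(cfg, "dropout_config"), cfg$n_samples >= 1)
  params <- params %||% generator$params
  nz <- generator$spec$noise_dim
  z0 <- with_stream(cfg$seed, "z", 0, rnorm(nz))
  lapply(seq_len(cfg$n_samples) - 1L, function(i) {
    th <- sample_configuration(params, cfg, i)
    z <- if (resample_z) with_stream(cfg$seed, "z", i, rnorm(nz)) else z0
    p <- gen_forward(generator$spec, th, x, z)$probs
    if (any(!is.finite(p))) abort(sprintf("non-finite output in member %d", i))
    p
  })
}

check_maps <- function(samples) {
  if (length(samples) == 0) abort("at least one probability map is required")
  d <- dim(samples[[1]])
  for (s in samples) if (!all(dim(s) == d)) abort("inconsistent map shapes")
  d
}

#' First predictive moment (Monte-Carlo mean)
#'
#' The aggregate prediction \eqn{E_{q(y|x)}[y] \approx \frac1N \sum_i
#' \hat y(x, \hat\theta_i)}: the elementwise mean of the member maps, itself a
#' valid per-pixel probability map.
#'
#' @param samples list of H x W x C probability arrays.
#' @return H x W x C array.
#' @export
predictive_mean <- function(samples) {
  d <- check_maps(samples)
  out <- samples[[1]]
  if (length(samples) > 1) for (s in samples[-1]) out <- out + s
  out / length(samples)
}

#' Second predictive moment (per-pixel uncertainty matrix)
#'
#' Per pixel, \eqn{u \approx \mathrm{diag}(1/\tau) + \frac1N\sum_i \hat y_i^T
#' \hat y_i - E[y]^T E[y]}: a C x C matrix whose data-dependent part is the
#' (positive semidefinite) covariance of the member predictions and whose
#' constant part encodes class rarity.
#'
#' @param samples list of H x W x C probability arrays.
#' @param freq a [class_frequency_spec] with `freq$C == C`.
#' @param diagonal_only return only the H x W x C diagonal (memory saver)?
#' @return H x W x C x C array `u` (or H x W x C if `diagonal_only`).
#' @export
predictive_uncertainty <- function(samples, freq, diagonal_only = FALSE) {
  stopifnot(inherits(freq, "class_frequency_spec"))
  d <- check_maps(samples)
  C <- d[3]
  if (freq$C != C) abort("`freq$C` does not match the class count of the maps")
  inv_tau <- tau_inverse_diag(freq)
  N <- length(samples)
  m <- predictive_mean(samples)
  # N identical configurations carry zero disagreement by definition; the
  # covariance part is evaluated in centered form for numerical stability
  degenerate <- all_identical_maps(samples)
  if (diagonal_only) {
    u <- array(rep(inv_tau, each = d[1] * d[2]), dim = d)
    if (!degenerate) {
      sec <- array(0, dim = d)
      for (s in samples) sec <- sec + (s - m)^2
      u <- u + sec / N
    }
    return(u)
  }
  u <- array(0, dim = c(d[1], d[2], C, C))
  for (a in seq_len(C)) {
    for (b in seq_len(a)) {
      v <- if (degenerate) matrix(0, d[1], d[2]) else {
        sec <- 0
        for (s in samples) sec <- sec + (s[, , a] - m[, , a]) * (s[, , b] - m[, , b])
        sec / N
      }
      if (a == b) v <- v + inv_tau[a]
      u[, , a, b] <- v
      u[, , b, a] <- v
    }
  }
  u
}

all_identical_maps <- function(samples) {
  for (s in samples[-1]) if (!identical(s, samples[[1]])) return(FALSE)
  TRUE
}

# spatial map of trace(u - diag(1/tau)): total member disagreement per pixel
disagreement_map <- function(samples) {
  d <- check_maps(samples)
  if (all_identical_maps(samples)) return(matrix(0, d[1], d[2]))
  N <- length(samples)
  m <- predictive_mean(samples)
  sec <- array(0, dim = d)
  for (s in samples) sec <- sec + (s - m)^2
  apply(sec / N, c(1, 2), sum)
}

#' Predictive moments of one image
#'
#' Convenience wrapper computing the Monte-Carlo mean, the uncertainty matrix
#' and the scalar OOD score in one pass.
#'
#' @param samples list of member probability maps (from [mc_predict()]).
#' @param freq a [class_frequency_spec].
#' @param reduction,q passed to [ood_score()].
#' @return An object of class `predictive_moments`: list with `mean`, `u`,
#'   `ood_score`.
#' @export
predictive_moments <- function(samples, freq, reduction = "mean", q = NULL) {
  m <- predictive_mean(samples)
  u <- predictive_uncertainty(samples, freq)
  structure(list(mean = m, u = u,
                 ood_score = ood_score_from_samples(samples, reduction, q),
                 freq = freq),
            class = "predictive_moments")
}

ood_score_from_samples <- function(samples, reduction = "mean", q = NULL) {
  v <- disagreement_map(samples)
  reduce_field(v, reduction, q)
}

reduce_field <- function(v, reduction = c("mean", "max", "quantile"), q = NULL) {
  reduction <- match.arg(reduction)
  switch(reduction,
         mean = mean(v),
         max = max(v),
         quantile = {
           if (is.null(q)) abort("`q` is required for quantile reduction")
           as.numeric(quantile(v, q))
         })
}

#' Scalar out-of-distribution score
#'
#' Reduces the per-pixel total predictive variance
#' \eqn{\mathrm{tr}(u - \mathrm{diag}(1/\tau))} over the image. The constant
#' class-frequency offset is excluded so that confidently and consistently
#' predicted in-distribution pixels score near zero; what remains is pure
#' model disagreement, which rises on inputs unlike the training data.
#'
#' @param moments a `predictive_moments` object (or the output list of
#'   [mc_predict()], in which case the score is computed directly).
#' @param reduction `"mean"` (default), `"max"` or `"quantile"`.
#' @param q quantile for `reduction = "quantile"`.
#' @return A non-negative scalar.
#' @export
ood_score <- function(moments, reduction = "mean", q = NULL) {
  if (inherits(moments, "predictive_moments")) {
    inv_tau <- tau_inverse_diag(moments$freq)
    d <- dim(moments$u)
    tr <- 0
    for (c in seq_len(d[3])) tr <- tr + moments$u[, , c, c] - inv_tau[c]
    v <- pmax(tr, 0)
    return(reduce_field(v, reduction, q))
  }
  ood_score_from_samples(moments, reduction, q)
}

#' @export
print.predictive_moments <- function(x, ...) {
  d <- dim(x$mean)
  cat(sprintf("<predictive_moments> %dx%d image, %d classes, ood_score = %.4g\n",
              d[1], d[2], d[3], x$ood_score))
  invisible(x)
}

#' Per-image OOD scores for a dataset
#'
#' @param fit a trained `begas_fit` (or an `hourglass_generator`).
#' @param samples list of [image_sample] objects.
#' @param cfg a [dropout_config] controlling N and sigma at prediction time.
#' @param reduction,q passed to [ood_score()].
#' @param resample_z passed to [mc_predict()]: with `TRUE`, members differ in
#'   z as well as weights, so the score also captures the generator's
#'   conditional instability.
#' @return A tibble with `sample_id`, `domain_tag`, `score`.
#' @export
ood_scores <- function(fit, samples, cfg = NULL, reduction = "mean", q = NULL,
                       resample_z = FALSE) {
  gen <- if (inherits(fit, "begas_fit")) fit$generator else fit
  cfg <- cfg %||% (if (inherits(fit, "begas_fit")) fit$cfg$dropout else dropout_config())
  tibble(
    sample_id = vapply(samples, function(s) s$sample_id, character(1)),
    domain_tag = vapply(samples, function(s) s$domain_tag, character(1)),
    score = vapply(samples, function(s) {
      maps <- mc_predict(gen, s$image, cfg, resample_z = resample_z)
      ood_score_from_samples(maps, reduction, q)
    }, numeric(1))
  )
}
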