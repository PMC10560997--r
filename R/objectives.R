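#' Ensemble objective configuration
#'
#' Configures the multi-discriminator objective: `K` discriminators, their
#' weights \eqn{\lambda_k}, the auxiliary segmentation loss each one is paired
#' with, and the stochastic feedback aggregation. At the end of every batch
#' the aggregation mode F (sum, average or maximum of the per-discriminator
#' adversarial values) is redrawn from `mode_probs`, and each discriminator's
#' feedback is independently dropped with probability `drop_prob` (resampled
#' if all K would drop), so the generator only sees the remaining
#' discriminators that batch.
#'
#' @param K number of discriminators (`>= 1`).
#' @param lambda_k per-discriminator weights (`>= 0`), recycled to length K.
#' @param loss_assignment per-discriminator auxiliary loss, each one of
#'   `"mae"`, `"cce"`, `"dice"`; recycled to length K.
#' @param aggregation_mode fixed mode used when `mode_probs` is degenerate;
#'   one of `"sum"`, `"average"`, `"maximum"`.
#' @param mode_probs named probabilities over the three modes (sum to 1);
#'   default uniform.
#' @param drop_prob probability a discriminator's feedback is omitted for a
#'   batch, in `[0, 1)`.
#' @param adversarial `"non_saturating"` (generator minimises
#'   \eqn{-\log D(\mathrm{fake})}; default) or `"saturating"` (the literal
#'   \eqn{\log(1 - D(\mathrm{fake}))} form of the value function).
#' @param aux_weights named weights of the auxiliary losses. The default of
#'   10 per loss keeps the supervised segmentation signal dominant over the
#'   adversarial feedback, the usual balance in conditional image-to-image
#'   adversarial training; with equal weighting the patch discriminators
#'   reward crisp background-only predictions early in training and the
#'   generator collapses to the majority class.
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(K = 3,
                             lambda_k = 1,
                             loss_assignment = c("mae", "cce", "dice"),
                             aggregation_mode = c("average", "sum", "maximum"),
                             mode_probs = c(sum = 1 / 3, average = 1 / 3, maximum = 1 / 3),
                             drop_prob = 0.1,
                             adversarial = c("non_saturating", "saturating"),
                             aux_weights = c(mae = 10, cce = 10, dice = 10)) {
  stopifnot(K >= 1, drop_prob >= 0, drop_prob < 1)
  aggregation_mode <- match.arg(aggregation_mode)
  adversarial <- match.arg(adversarial)
  lambda_k <- rep_len(lambda_k, K)
  if (any(lambda_k < 0)) abort("`lambda_k` must be >= 0")
  loss_assignment <- rep_len(loss_assignment, K)
  stopifnot(all(loss_assignment %in% c("mae", "cce", "dice")))
  if (abs(sum(mode_probs) - 1) > 1e-6) abort("`mode_probs` must sum to 1")
  mode_probs <- mode_probs / sum(mode_probs)
  if (!identical(sort(names(mode_probs)), c("average", "maximum", "sum"))) {
    abort("`mode_probs` must be named with sum/average/maximum")
  }
  if (is.null(names(aux_weights)) ||
      !all(c("mae", "cce", "dice") %in% names(aux_weights))) {
    abort("`aux_weights` must be named with mae/cce/dice")
  }
  structure(list(K = as.integer(K), lambda_k = lambda_k,
                 loss_assignment = loss_assignment,
                 aggregation_mode = aggregation_mode,
                 mode_probs = mode_probs, drop_prob = drop_prob,
                 adversarial = adversarial, aux_weights = aux_weights),
            class = "objective_config")
}

as_onehot <- function(mask, C) {
  H <- nrow(mask); W <- ncol(mask)
  out <- array(0, dim = c(H, W, C))
  idx <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H),
               as.vector(mask) + 1L)
  out[idx] <- 1
  out
}

check_simplex <- function(pred, tol = 1e-5) {
  d <- dim(pred)
  s <- matrix(pred, ncol = d[3])
  if (any(s < -tol) || any(abs(rowSums(s) - 1) > tol)) {
    abort("`pred` must be a per-pixel probability simplex")
  }
}

#' Dice loss
#'
#' \eqn{\ell_{Dice} = 1 - \frac{2\sum p\,t + \epsilon}{\sum p + \sum t +
#' \epsilon}} with \eqn{\epsilon = 10^{-6}}, averaged over foreground classes
#' (class index 0 is treated as background and excluded).
#'
#' @param pred H x W x C per-pixel probability map.
#' @param target H x W x C one-hot mask (or an integer H x W mask).
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, target) {
  if (is.matrix(target)) target <- as_onehot(target, dim(pred)[3])
  stopifnot(all(dim(pred) == dim(target)))
  check_simplex(pred)
  dice_raw(pred, target)
}

# formula without the simplex guard (shared with gradient checking)
dice_raw <- function(pred, target) {
  eps <- 1e-6
  C <- dim(pred)[3]
  fg <- if (C > 1) seq.int(2, C) else 1L
  vals <- vapply(fg, function(c) {
    p <- pred[, , c]; t <- target[, , c]
    1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  }, numeric(1))
  mean(vals)
}

dice_loss_grad <- function(pred, target) {
  eps <- 1e-6
  C <- dim(pred)[3]
  fg <- if (C > 1) seq.int(2, C) else 1L
  g <- array(0, dim = dim(pred))
  for (c in fg) {
    p <- pred[, , c]; t <- target[, , c]
    num <- 2 * sum(p * t) + eps
    den <- sum(p) + sum(t) + eps
    g[, , c] <- -(2 * t * den - num) / den^2 / length(fg)
  }
  g
}

#' Mean absolute error loss
#'
#' @param pred,target arrays of identical shape.
#' @return Non-negative scalar: the elementwise mean of `|pred - target|`.
#' @export
mae_loss <- function(pred, target) {
  if (is.matrix(target) && length(dim(pred)) == 3) {
    target <- as_onehot(target, dim(pred)[3])
  }
  stopifnot(all(dim(pred) == dim(target)))
  mean(abs(pred - target))
}

mae_loss_grad <- function(pred, target) {
  sign(pred - target) / length(pred)
}

#' Categorical cross-entropy loss
#'
#' Mean per-pixel \eqn{-\log p(\mathrm{true\ class})}; probabilities are
#' clamped at `1e-12` (clamped pixels are counted in the `"clamped"`
#' attribute).
#'
#' @param pred H x W x C per-pixel probability map (simplex).
#' @param target H x W x C one-hot mask or integer H x W mask.
#' @return Non-negative scalar.
#' @export
cce_loss <- function(pred, target) {
  if (is.matrix(target)) target <- as_onehot(target, dim(pred)[3])
  stopifnot(all(dim(pred) == dim(target)))
  check_simplex(pred)
  p_true <- apply(pred * target, c(1, 2), sum)
  n_clamped <- sum(p_true < 1e-12)
  out <- mean(-log(pmax(p_true, 1e-12)))
  attr(out, "clamped") <- n_clamped
  out
}

cce_loss_grad <- function(pred, target) {
  npix <- prod(dim(pred)[1:2])
  -target / pmax(pred, 1e-7) / npix
}

aux_loss <- function(type, pred, target_onehot) {
  switch(type,
         mae = mae_loss(pred, target_onehot),
         cce = as.numeric(cce_loss(pred, target_onehot)),
         dice = dice_loss(pred, target_onehot))
}
aux_loss_grad <- function(type, pred, target_onehot) {
  switch(type,
         mae = mae_loss_grad(pred, target_onehot),
         cce = cce_loss_grad(pred, target_onehot),
         dice = dice_loss_grad(pred, target_onehot))
}

#' Adversarial value of one discriminator
#'
#' The value function
#' \eqn{V(D_k, G) = E[\log D_k(x,y)] + \lambda_k E[\log(1 - D_k(G(z,y), y))]},
#' with patch scores averaged to the batch expectation. Non-positive by
#' construction; a perfect discriminator drives it to 0 from below.
#'
#' @param d_scores_real,d_scores_fake patch score grids with entries in (0,1).
#' @param lambda_k weight of the fake term.
#' @return Scalar value.
#' @export
adversarial_value <- function(d_scores_real, d_scores_fake, lambda_k = 1) {
  if (any(d_scores_real <= 0 | d_scores_real >= 1) ||
      any(d_scores_fake <= 0 | d_scores_fake >= 1)) {
    abort("discriminator scores must lie in the open interval (0, 1)")
  }
  mean(log(d_scores_real)) + lambda_k * mean(log(1 - d_scores_fake))
}

#' Aggregate multi-discriminator feedback
#'
#' Applies the feedback aggregation F over the discriminators still active
#' this batch: the sum, average or maximum of their values.
#'
#' @param values numeric vector of K per-discriminator scalars.
#' @param mode `"sum"`, `"average"` or `"maximum"`.
#' @param active_mask logical vector of length K; at least one `TRUE`.
#' @return Scalar aggregated feedback.
#' @export
aggregate_feedback <- function(values, mode = c("sum", "average", "maximum"),
                               active_mask = rep(TRUE, length(values))) {
  mode <- match.arg(mode)
  stopifnot(length(active_mask) == length(values))
  v <- values[active_mask]
  if (length(v) == 0) abort("all discriminators dropped: at least one must remain")
  switch(mode, sum = sum(v), average = sum(v) / length(v), maximum = max(v))
}

# draw this batch's aggregation mode and active mask (resampling until at
# least one discriminator remains)
draw_batch_controls <- function(cfg, seed, counter) {
  with_stream(seed, "controls", counter, {
    mode <- sample(names(cfg$mode_probs), 1, prob = cfg$mode_probs)
    if (cfg$drop_prob == 0) {
      active <- rep(TRUE, cfg$K)
    } else {
      repeat {
        active <- runif(cfg$K) >= cfg$drop_prob
        if (any(active)) break
      }
    }
    list(mode = mode, active = active)
  })
}

#' Generator loss on one batch
#'
#' Evaluates (without updating anything) the generator objective on a batch:
#' the aggregated adversarial feedback of the active discriminators plus each
#' active discriminator's assigned auxiliary segmentation loss on the
#' predicted mask. With `K = 1` this reduces exactly to the conditional-GAN
#' objective.
#'
#' @param batch list of [image_sample] objects with masks.
#' @param generator an `hourglass_generator`.
#' @param discriminators list of K `patch_discriminator` objects.
#' @param cfg an [objective_config].
#' @param mode aggregation mode for this batch (default `cfg$aggregation_mode`).
#' @param active_mask logical length-K activity mask.
#' @param seed seed for z.
#' @return A list with `total` and a per-term `breakdown` tibble.
#' @export
generator_loss <- function(batch, generator, discriminators, cfg,
                           mode = NULL, active_mask = NULL, seed = 0) {
  stopifnot(inherits(cfg, "objective_config"),
            length(discriminators) == cfg$K)
  mode <- mode %||% cfg$aggregation_mode
  active_mask <- active_mask %||% rep(TRUE, cfg$K)
  C <- generator$spec$n_classes
  adv <- rep(NA_real_, cfg$K)
  aux <- rep(NA_real_, cfg$K)
  total <- 0
  for (b in seq_along(batch)) {
    s <- batch[[b]]
    z <- with_stream(seed, "z", b, rnorm(generator$spec$noise_dim))
    fw <- gen_forward(generator$spec, generator$params, s$image, z)
    y1h <- as_onehot(s$mask, C)
    adv_b <- numeric(cfg$K); aux_b <- numeric(cfg$K)
    for (k in seq_len(cfg$K)) {
      if (!active_mask[k]) next
      sc <- disc_forward(discriminators[[k]], discriminators[[k]]$params,
                         s$image, fw$probs)$scores
      sc <- pmin(pmax(sc, 1e-12), 1 - 1e-12)
      adv_b[k] <- if (cfg$adversarial == "non_saturating") {
        cfg$lambda_k[k] * mean(-log(sc))
      } else {
        cfg$lambda_k[k] * mean(log(1 - sc))
      }
      aux_b[k] <- cfg$aux_weights[[cfg$loss_assignment[k]]] *
        aux_loss(cfg$loss_assignment[k], fw$probs, y1h)
    }
    adv <- ifelse(active_mask, ifelse(is.na(adv), 0, adv) + adv_b, adv)
    aux <- ifelse(active_mask, ifelse(is.na(aux), 0, aux) + aux_b, aux)
    total <- total +
      aggregate_feedback(adv_b, mode, active_mask) + sum(aux_b[active_mask])
  }
  n <- length(batch)
  if (!is.finite(total)) abort("NaN/Inf in generator loss")
  breakdown <- tibble(
    discriminator = seq_len(cfg$K),
    active = active_mask,
    loss_type = cfg$loss_assignment,
    lambda = cfg$lambda_k,
    adversarial = adv / n,
    auxiliary = aux / n
  )
  bad <- which(!is.finite(breakdown$adversarial[active_mask]) |
                 !is.finite(breakdown$auxiliary[active_mask]))
  if (length(bad) > 0) {
    abort(paste0("non-finite loss term for discriminator(s) ",
                 paste(which(active_mask)[bad], collapse = ", ")))
  }
  list(total = total / n, breakdown = breakdown, mode = mode)
}
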