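#' Training configuration
#'
#' Defaults follow the adversarial-training recipe used throughout: Adam with
#' learning rate 2e-4, \eqn{\beta_1 = 0.9}, \eqn{\beta_2 = 0.999}, weight
#' decay 1e-4, mini-batch size 1.
#'
#' @param epochs number of passes over the training set.
#' @param seed master seed; every random stream of the run derives from it.
#' @param learning_rate initial Adam learning rate (`> 0`).
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param weight_decay L2 weight decay coefficient.
#' @param batch_size mini-batch size (`>= 1`).
#' @param dropout a [dropout_config] (weight-noise sigma, MC sample count N).
#' @param objective an [objective_config] (K discriminators, lambdas, modes).
#' @param dropout_at_train apply the weight noise during training as well as
#'   at test time?
#' @param lr_schedule `"constant"` (default) or `"linear_decay"` to
#'   `lr_final` over the epochs.
#' @param lr_final final learning rate for `"linear_decay"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 5, seed = 0, learning_rate = 2e-4,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         weight_decay = 1e-4, batch_size = 1,
                         dropout = dropout_config(),
                         objective = objective_config(),
                         dropout_at_train = TRUE,
                         lr_schedule = c("constant", "linear_decay"),
                         lr_final = 0) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  lr_schedule <- match.arg(lr_schedule)
  structure(list(epochs = as.integer(epochs), seed = as.integer(seed),
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 objective = objective, dropout_at_train = dropout_at_train,
                 lr_schedule = lr_schedule, lr_final = lr_final),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params$theta, function(a) a * 0),
       v = lapply(params$theta, function(a) a * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, b1, b2, wd, eps = 1e-8) {
  state$t <- state$t + 1L
  theta <- params$theta
  for (nm in names(theta)) {
    g <- grads[[nm]] + wd * theta[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = network_parameters(theta), state = state)
}

lr_at <- function(cfg, progress) {
  if (cfg$lr_schedule == "constant") return(cfg$learning_rate)
  cfg$learning_rate + (cfg$lr_final - cfg$learning_rate) * progress
}

clamp01 <- function(s) pmin(pmax(s, 1e-12), 1 - 1e-12)

# one discriminator BCE update on a (real, fake) pair; returns loss + params
disc_step <- function(disc, x, y_real, y_fake, state, lr, cfg) {
  fr <- disc_forward(disc, disc$params, x, y_real, want_cache = TRUE)
  n <- length(fr$scores)
  sr <- clamp01(fr$scores)
  br <- disc_backward(disc, disc$params, fr$cache, (sr - 1) / n)
  ff <- disc_forward(disc, disc$params, x, y_fake, want_cache = TRUE)
  sf <- clamp01(ff$scores)
  bf <- disc_backward(disc, disc$params, ff$cache, sf / n)
  grads <- br$grads
  for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + bf$grads[[nm]]
  loss <- -mean(log(sr)) - mean(log(1 - sf))
  up <- adam_update(disc$params, grads, state, lr, cfg$adam_beta1,
                    cfg$adam_beta2, cfg$weight_decay)
  disc$params <- up$params
  list(disc = disc, state = up$state, loss = loss)
}

# adversarial value and generator-side gradient at the discriminator's
# score grid, for one discriminator
gen_adv_terms <- function(disc, x, probs, lambda, adversarial) {
  fw <- disc_forward(disc, disc$params, x, probs, want_cache = TRUE)
  s <- clamp01(fw$scores)
  n <- length(s)
  if (adversarial == "non_saturating") {
    value <- lambda * mean(-log(s))
    gLogits <- -lambda * (1 - s) / n
  } else {
    value <- lambda * mean(log(1 - s))
    gLogits <- -lambda * s / n
  }
  bw <- disc_backward(disc, disc$params, fw$cache, gLogits)
  gy <- bw$gx_input[, , disc$image_channels + seq_len(disc$n_classes), drop = FALSE]
  list(value = value, gProbs = gy)
}

# per-mode gradient weights over the active adversarial values
aggregation_weights <- function(values, mode, active) {
  w <- numeric(length(values))
  idx <- which(active)
  if (mode == "sum") {
    w[idx] <- 1
  } else if (mode == "average") {
    w[idx] <- 1 / length(idx)
  } else {
    w[idx[which.max(values[idx])]] <- 1
  }
  w
}

new_history_row <- function(epoch, iter, sample_id, mode, active, sigma,
                            d_loss, adv, aux, gen_total) {
  sum_adv <- sum(adv, na.rm = TRUE)
  sum_aux <- sum(aux, na.rm = TRUE)
  tibble(epoch = epoch, iter = iter, sample_id = sample_id, mode = mode,
         active = paste(as.integer(active), collapse = ""), sigma = sigma,
         d_loss = list(d_loss), adv = list(adv), aux = list(aux),
         gen_adv = sum_adv, gen_aux = sum_aux, gen_total = gen_total)
}

quick_f1 <- function(spec, params, samples, seed) {
  z <- with_stream(seed, "val_z", 0, rnorm(spec$noise_dim))
  f1s <- vapply(samples, function(s) {
    p <- gen_forward(spec, params, s$image, z)$probs
    pred <- apply(p, c(1, 2), which.max) - 1L
    vals <- vapply(seq_len(spec$n_classes - 1), function(ci) {
      confusion_scores(pred, s$mask, ci)$f1
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

#' Train the Bayesian ensemble adversarial framework
#'
#' Alternates, per mini-batch, one BCE step for every discriminator (real
#' pair vs. the generator's current prediction) and one generator step whose
#' objective is the aggregated adversarial feedback of the active
#' discriminators plus their assigned auxiliary segmentation losses. The
#' aggregation mode is redrawn per batch from `mode_probs`, and each
#' discriminator's feedback is dropped with probability `drop_prob`
#' (discriminators keep training while dropped; only the generator stops
#' listening to them). With weight noise enabled the generator trains through
#' perturbed configurations \eqn{\hat\theta = \theta \cdot \delta}, gradients
#' chained through \eqn{\delta}.
#'
#' Fully reproducible: every random draw comes from a named counter-indexed
#' stream under `cfg$seed`, so identical configurations give identical
#' histories.
#'
#' @param train_set,val_set lists of masked [image_sample] objects
#'   (`val_set` may be `NULL`).
#' @param generator_spec a [generator_spec].
#' @param discriminator_specs list of K [discriminator_spec] objects
#'   (K must match `cfg$objective$K`).
#' @param cfg a [train_config].
#' @return An object of class `begas_fit`: generator, discriminators,
#'   `history` (per-iteration tibble with the chosen aggregation mode and
#'   active mask), per-epoch validation F1, training-class frequencies, and
#'   the configuration. On divergence, aborts with the last finite
#'   checkpoint attached to the condition.
#' @export
train <- function(train_set, val_set = NULL, generator_spec,
                  discriminator_specs, cfg = train_config()) {
  stopifnot(length(train_set) >= 1,
            length(discriminator_specs) == cfg$objective$K)
  obj <- cfg$objective
  C <- generator_spec$n_classes
  gen <- build_generator(generator_spec, seed = substream_seed(cfg$seed, "gen_init", 0))
  discs <- lapply(seq_len(obj$K), function(k) {
    build_discriminator(discriminator_specs[[k]],
                        image_channels = generator_spec$input_channels,
                        n_classes = C,
                        seed = substream_seed(cfg$seed, "disc_init", k))
  })
  g_state <- adam_init(gen$params)
  d_states <- lapply(discs, function(d) adam_init(d$params))
  freq <- class_frequencies(train_set, C)
  n <- length(train_set)
  iters_per_epoch <- ceiling(n / cfg$batch_size)
  total_iters <- cfg$epochs * iters_per_epoch
  history <- vector("list", total_iters)
  val_log <- list()
  best <- list(f1 = -Inf, params = gen$params, epoch = 0L)
  iter <- 0L
  last_good <- gen$params
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_stream(cfg$seed, "order", epoch, sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (bi in seq_along(batches)) {
      iter <- iter + 1L
      progress <- (iter - 1) / max(total_iters - 1, 1)
      lr <- lr_at(cfg, progress)
      ctl <- draw_batch_controls(obj, cfg$seed, iter)
      sig <- if (cfg$dropout_at_train) sigma_at(cfg$dropout, progress) else 0
      theta_hat <- gen$params
      delta_cfg <- NULL
      if (sig > 0) {
        delta_cfg <- dropout_config(sigma = sig, n_samples = 1,
                                    seed = substream_seed(cfg$seed, "train_dropout", iter))
        theta_hat <- sample_configuration(gen$params, delta_cfg, 0)
      }
      g_grads <- NULL
      d_loss <- rep(NA_real_, obj$K)
      adv_vals <- rep(NA_real_, obj$K)
      aux_vals <- rep(NA_real_, obj$K)
      gen_total <- 0
      for (si in batches[[bi]]) {
        s <- train_set[[si]]
        z <- with_stream(cfg$seed, "z", iter * cfg$batch_size + match(si, batches[[bi]]),
                         rnorm(generator_spec$noise_dim))
        fw <- gen_forward(generator_spec, theta_hat, s$image, z, want_cache = TRUE)
        y1h <- as_onehot(s$mask, C)
        # --- discriminator updates (all K, every batch)
        for (k in seq_len(obj$K)) {
          st <- disc_step(discs[[k]], s$image, y1h, fw$probs, d_states[[k]], lr, cfg)
          discs[[k]] <- st$disc
          d_states[[k]] <- st$state
          d_loss[k] <- if (is.na(d_loss[k])) st$loss else d_loss[k] + st$loss
        }
        # --- generator update against the refreshed discriminators
        terms <- vector("list", obj$K)
        vals <- rep(NA_real_, obj$K)
        for (k in which(ctl$active)) {
          terms[[k]] <- gen_adv_terms(discs[[k]], s$image, fw$probs,
                                      obj$lambda_k[k], obj$adversarial)
          vals[k] <- terms[[k]]$value
        }
        wts <- aggregation_weights(vals, ctl$mode, ctl$active)
        gP <- array(0, dim = dim(fw$probs))
        for (k in which(ctl$active)) {
          if (wts[k] != 0) gP <- gP + wts[k] * terms[[k]]$gProbs
        }
        aux_b <- rep(0, obj$K)
        for (k in which(ctl$active)) {
          w <- obj$aux_weights[[obj$loss_assignment[k]]]
          aux_b[k] <- w * aux_loss(obj$loss_assignment[k], fw$probs, y1h)
          gP <- gP + w * aux_loss_grad(obj$loss_assignment[k], fw$probs, y1h)
        }
        adv_vals[ctl$active] <- ifelse(is.na(adv_vals[ctl$active]), 0,
                                       adv_vals[ctl$active]) + vals[ctl$active]
        aux_vals[ctl$active] <- ifelse(is.na(aux_vals[ctl$active]), 0,
                                       aux_vals[ctl$active]) + aux_b[ctl$active]
        gen_total <- gen_total +
          aggregate_feedback(vals, ctl$mode, ctl$active) + sum(aux_b[ctl$active])
        gL <- softmax3_bw(fw$probs, gP)
        gb <- gen_backward(generator_spec, theta_hat, fw$cache, gL)
        if (is.null(g_grads)) g_grads <- gb else {
          for (nm in names(gb)) g_grads[[nm]] <- g_grads[[nm]] + gb[[nm]]
        }
      }
      nb <- length(batches[[bi]])
      if (nb > 1) for (nm in names(g_grads)) g_grads[[nm]] <- g_grads[[nm]] / nb
      if (!is.null(delta_cfg)) {
        # chain rule through theta_hat = theta * delta
        delta <- with_stream(delta_cfg$seed, "dropout", 0, {
          lapply(gen$params$theta, function(a)
            array(rnorm(length(a), 1, sig), dim = dim(a) %||% length(a)))
        })
        for (nm in names(g_grads)) g_grads[[nm]] <- g_grads[[nm]] * delta[[nm]]
      }
      bad <- !all(vapply(g_grads, function(g) all(is.finite(g)), logical(1)))
      if (bad || !is.finite(gen_total)) {
        abort(sprintf("training diverged at epoch %d iter %d (non-finite loss)",
                      epoch, iter),
              class = "begas_divergence", last_good = last_good)
      }
      up <- adam_update(gen$params, g_grads, g_state, lr, cfg$adam_beta1,
                        cfg$adam_beta2, cfg$weight_decay)
      gen$params <- up$params
      g_state <- up$state
      last_good <- gen$params
      history[[iter]] <- new_history_row(
        epoch, iter, paste(vapply(batches[[bi]], function(si) train_set[[si]]$sample_id,
                                  character(1)), collapse = ","),
        ctl$mode, ctl$active, sig, d_loss / nb, adv_vals / nb, aux_vals / nb,
        gen_total / nb)
    }
    if (!is.null(val_set) && length(val_set) > 0) {
      f1 <- quick_f1(generator_spec, gen$params, val_set, cfg$seed)
      val_log[[epoch]] <- tibble(epoch = epoch, val_f1 = f1)
      if (f1 > best$f1) best <- list(f1 = f1, params = gen$params, epoch = epoch)
    }
  }
  history <- dplyr::bind_rows(history)
  class(history) <- c("train_history", class(history))
  structure(list(generator = gen, discriminators = discs,
                 history = history,
                 validation = if (length(val_log)) dplyr::bind_rows(val_log) else NULL,
                 best = list(epoch = best$epoch, val_f1 = best$f1,
                             params = if (is.finite(best$f1)) best$params else NULL),
                 freq = freq, cfg = cfg,
                 class_names = attr(train_set, "spec")$class_names),
            class = "begas_fit")
}

#' Train a standalone conditional GAN baseline
#'
#' An independent single-discriminator conditional-GAN training loop: no
#' ensemble feedback aggregation, no discriminator dropping, no weight
#' noise. Serves as the reference the framework must reduce to when
#' `K = 1`, `sigma = 0`, `drop_prob = 0`.
#'
#' @param train_set list of masked [image_sample] objects.
#' @param generator_spec a [generator_spec].
#' @param discriminator_spec a single [discriminator_spec].
#' @param cfg a [train_config] (its `objective$lambda_k[1]`,
#'   `loss_assignment[1]`, `adversarial` and Adam settings are honoured).
#' @return A `begas_fit`-shaped list of class `cgan_fit` with the trained
#'   generator, discriminator and per-iteration history.
#' @export
train_cgan <- function(train_set, generator_spec, discriminator_spec,
                       cfg = train_config(objective = objective_config(K = 1))) {
  obj <- cfg$objective
  C <- generator_spec$n_classes
  gen <- build_generator(generator_spec, seed = substream_seed(cfg$seed, "gen_init", 0))
  disc <- build_discriminator(discriminator_spec,
                              image_channels = generator_spec$input_channels,
                              n_classes = C,
                              seed = substream_seed(cfg$seed, "disc_init", 1))
  g_state <- adam_init(gen$params)
  d_state <- adam_init(disc$params)
  n <- length(train_set)
  iters_per_epoch <- ceiling(n / cfg$batch_size)
  total_iters <- cfg$epochs * iters_per_epoch
  history <- vector("list", total_iters)
  iter <- 0L
  lambda <- obj$lambda_k[1]
  aux_type <- obj$loss_assignment[1]
  aux_w <- obj$aux_weights[[aux_type]]
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_stream(cfg$seed, "order", epoch, sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (bi in seq_along(batches)) {
      iter <- iter + 1L
      progress <- (iter - 1) / max(total_iters - 1, 1)
      lr <- lr_at(cfg, progress)
      g_grads <- NULL
      d_loss <- 0; adv_val <- 0; aux_val <- 0
      for (si in batches[[bi]]) {
        s <- train_set[[si]]
        z <- with_stream(cfg$seed, "z", iter * cfg$batch_size + match(si, batches[[bi]]),
                         rnorm(generator_spec$noise_dim))
        fw <- gen_forward(generator_spec, gen$params, s$image, z, want_cache = TRUE)
        y1h <- as_onehot(s$mask, C)
        st <- disc_step(disc, s$image, y1h, fw$probs, d_state, lr, cfg)
        disc <- st$disc; d_state <- st$state
        d_loss <- d_loss + st$loss
        tm <- gen_adv_terms(disc, s$image, fw$probs, lambda, obj$adversarial)
        adv_val <- adv_val + tm$value
        gP <- array(0, dim = dim(fw$probs))
        gP <- gP + 1 * tm$gProbs
        aux_val <- aux_val + aux_w * aux_loss(aux_type, fw$probs, y1h)
        gP <- gP + aux_w * aux_loss_grad(aux_type, fw$probs, y1h)
        gL <- softmax3_bw(fw$probs, gP)
        gb <- gen_backward(generator_spec, gen$params, fw$cache, gL)
        if (is.null(g_grads)) g_grads <- gb else {
          for (nm in names(gb)) g_grads[[nm]] <- g_grads[[nm]] + gb[[nm]]
        }
      }
      nb <- length(batches[[bi]])
      if (nb > 1) for (nm in names(g_grads)) g_grads[[nm]] <- g_grads[[nm]] / nb
      up <- adam_update(gen$params, g_grads, g_state, lr, cfg$adam_beta1,
                        cfg$adam_beta2, cfg$weight_decay)
      gen$params <- up$params
      g_state <- up$state
      history[[iter]] <- new_history_row(
        epoch, iter, paste(vapply(batches[[bi]], function(si) train_set[[si]]$sample_id,
                                  character(1)), collapse = ","),
        "single", TRUE, 0, d_loss / nb, adv_val / nb, aux_val / nb,
        (adv_val + aux_val) / nb)
    }
  }
  history <- dplyr::bind_rows(history)
  class(history) <- c("train_history", class(history))
  structure(list(generator = gen, discriminators = list(disc),
                 history = history, freq = class_frequencies(train_set, C),
                 cfg = cfg,
                 class_names = attr(train_set, "spec")$class_names),
            class = c("cgan_fit", "begas_fit"))
}

#' Repeated 80/20 cross-validated evaluation
#'
#' Performs `k` repeated seeded random 80/20 train/validation splits (three
#' by default), trains the framework on each training portion and evaluates
#' on the held-out portion.
#'
#' @param dataset a masked `phantom_dataset` (size `>= k`).
#' @param generator_spec,discriminator_specs passed to [train()].
#' @param cfg a [train_config]; split `r` trains under a seed derived from
#'   `(cfg$seed, r)`.
#' @param k number of repeated splits.
#' @return A list with `reports` (one [evaluate_model()] report per split)
#'   and `summary` (a tibble with mean and sd of macro precision/recall/F1/
#'   ASSD across splits).
#' @export
cross_validate <- function(dataset, generator_spec, discriminator_specs,
                           cfg = train_config(), k = 3) {
  n <- length(dataset)
  stopifnot(n >= k, n >= 5)
  C <- generator_spec$n_classes
  reports <- vector("list", k)
  for (r in seq_len(k)) {
    idx <- with_stream(cfg$seed, "cv_split", r, sample.int(n))
    n_val <- max(1, round(0.2 * n))
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- setdiff(idx, val_idx)
    tr <- dataset[tr_idx]
    attributes(tr) <- attributes(dataset)[c("class", "spec", "seed", "task")]
    present <- sort(unique(unlist(lapply(tr, function(s) unique(as.vector(s$mask))))))
    missing <- setdiff(seq_len(C) - 1L, present)
    if (length(missing) > 0) {
      abort(paste0("classes absent from training split ", r, ": ",
                   paste(missing, collapse = ", ")))
    }
    cfg_r <- cfg
    cfg_r$seed <- substream_seed(cfg$seed, "cv_seed", r)
    fit <- train(tr, dataset[val_idx], generator_spec, discriminator_specs, cfg_r)
    rep <- evaluate_model(fit, dataset[val_idx], cfg$dropout)
    rep$fold <- r
    reports[[r]] <- rep
  }
  macro <- dplyr::bind_rows(lapply(reports, function(r)
    dplyr::filter(as_tibble(r), .data$class == "macro")))
  summary <- tibble(
    metric = c("precision", "recall", "f1", "assd", "ece", "nll"),
    mean = c(mean(macro$precision), mean(macro$recall), mean(macro$f1),
             mean(macro$assd), mean(macro$ece), mean(macro$nll)),
    sd = c(sd(macro$precision), sd(macro$recall), sd(macro$f1),
           sd(macro$assd), sd(macro$ece), sd(macro$nll))
  )
  list(reports = reports, summary = summary)
}

#' Mean per-class diagonal uncertainty of a dataset
#'
#' For each class c, averages the diagonal entry `u[c, c]` of the per-pixel
#' uncertainty matrix over the pixels whose true label is c. The
#' class-frequency offset `1/tau_c` is part of `u`, so rare classes carry a
#' rarity floor on top of the model-disagreement component (also reported
#' separately as `disagreement`).
#'
#' @param fit a `begas_fit`.
#' @param samples masked [image_sample] list.
#' @param cfg optional [dropout_config] override.
#' @return A tibble with `class`, `mean_u`, `disagreement`, `n_pixels`.
#' @export
class_uncertainty <- function(fit, samples, cfg = NULL) {
  cfg <- cfg %||% fit$cfg$dropout
  C <- fit$generator$spec$n_classes
  sums <- numeric(C); dis <- numeric(C); npx <- numeric(C)
  inv_tau <- tau_inverse_diag(fit$freq)
  for (s in samples) {
    maps <- mc_predict(fit$generator, s$image, cfg)
    ud <- predictive_uncertainty(maps, fit$freq, diagonal_only = TRUE)
    for (c in seq_len(C)) {
      sel <- s$mask == (c - 1L)
      if (!any(sel)) next
      u_c <- ud[, , c][sel]
      sums[c] <- sums[c] + sum(u_c)
      dis[c] <- dis[c] + sum(u_c - inv_tau[c])
      npx[c] <- npx[c] + sum(sel)
    }
  }
  tibble(class = fit$class_names %||% paste0("class_", seq_len(C) - 1),
         mean_u = sums / pmax(npx, 1),
         disagreement = dis / pmax(npx, 1),
         n_pixels = npx)
}

#' @export
print.begas_fit <- function(x, ...) {
  cat("<begas_fit>", x$cfg$objective$K, "discriminator(s),",
      x$cfg$epochs, "epochs,", nrow(x$history), "iterations\n")
  if (!is.null(x$validation)) {
    cat("  best val F1:", format(x$best$val_f1, digits = 4),
        "at epoch", x$best$epoch, "\n")
  }
  invisible(x)
}

#' @rdname tidy.begas_fit
#' @export
tidy.begas_fit <- function(x, ...) {
  h <- x$history
  tibble::as_tibble(h[, c("epoch", "iter", "mode", "active", "sigma",
                          "gen_adv", "gen_aux", "gen_total")])
}

#' Tidy and glance methods for fitted frameworks
#'
#' `tidy()` returns the per-iteration loss trajectory; `glance()` a one-row
#' run summary.
#'
#' @param x a `begas_fit`.
#' @param ... unused.
#' @return A tibble.
#' @export
glance.begas_fit <- function(x, ...) {
  h <- x$history
  tibble(
    K = x$cfg$objective$K,
    epochs = x$cfg$epochs,
    iterations = nrow(h),
    sigma = x$cfg$dropout$sigma,
    n_mc = x$cfg$dropout$n_samples,
    final_gen_total = h$gen_total[nrow(h)],
    final_gen_aux = h$gen_aux[nrow(h)],
    best_val_f1 = if (!is.null(x$validation)) x$best$val_f1 else NA_real_
  )
}
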