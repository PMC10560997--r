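tiny_setup <- function(n = 8, seed = 4) {
  list(
    ds = generate_segmentation_dataset(phantom_preset("desk", c(32, 32)), n, seed = seed),
    gspec = generator_spec(n_classes = 3, base_channels = 4, noise_dim = 4),
    dspecs = list(discriminator_spec(16, 4, "mae"),
                  discriminator_spec(16, 4, "cce"),
                  discriminator_spec(16, 4, "dice"))
  )
}

test_that("identical seeds yield identical training histories", {
  s <- tiny_setup()
  cfg <- train_config(epochs = 1, seed = 11,
                      dropout = dropout_config(sigma = 0.1, n_samples = 2, seed = 11))
  f1 <- train(s$ds, NULL, s$gspec, s$dspecs, cfg)
  f2 <- train(s$ds, NULL, s$gspec, s$dspecs, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$generator$params, f2$generator$params)
  f3 <- train(s$ds, NULL, s$gspec, s$dspecs,
              train_config(epochs = 1, seed = 12,
                           dropout = dropout_config(0.1, 2, seed = 12)))
  expect_false(identical(f1$history$gen_total, f3$history$gen_total))
})

test_that("the K = 1, sigma = 0 framework equals the standalone cGAN baseline", {
  s <- tiny_setup(n = 6)
  cfg <- train_config(
    epochs = 2, seed = 3,
    dropout = dropout_config(sigma = 0, n_samples = 1, seed = 3),
    objective = objective_config(K = 1, loss_assignment = "cce", drop_prob = 0))
  fa <- train(s$ds, NULL, s$gspec, s$dspecs[2], cfg)
  fb <- train_cgan(s$ds, s$gspec, s$dspecs[[2]], cfg)
  expect_identical(fa$history$gen_total, fb$history$gen_total)
  expect_identical(fa$history$gen_adv, fb$history$gen_adv)
  expect_identical(unlist(fa$history$d_loss), unlist(fb$history$d_loss))
  expect_identical(fa$generator$params, fb$generator$params)
})

test_that("aggregation-mode draws follow mode_probs and keep one discriminator", {
  probs <- c(sum = 0.5, average = 0.25, maximum = 0.25)
  obj <- objective_config(K = 3, mode_probs = probs, drop_prob = 0.3)
  draws <- lapply(1:400, function(i) begas:::draw_batch_controls(obj, 5, i))
  modes <- vapply(draws, function(d) d$mode, character(1))
  counts <- table(factor(modes, levels = names(probs)))
  p <- chisq.test(counts, p = probs)$p.value
  expect_gt(p, 0.01)
  expect_true(all(vapply(draws, function(d) any(d$active), logical(1))))
  # identical counters reproduce identical draws
  expect_identical(begas:::draw_batch_controls(obj, 5, 7),
                   begas:::draw_batch_controls(obj, 5, 7))
})

test_that("cross-validation arithmetic, disjointness and summary are correct", {
  ds <- generate_segmentation_dataset(phantom_preset("desk", c(32, 32)), 10, seed = 9)
  gspec <- generator_spec(n_classes = 3, base_channels = 2, noise_dim = 2)
  dspecs <- list(discriminator_spec(16, 2, "cce"))
  cfg <- train_config(epochs = 1, seed = 2,
                      dropout = dropout_config(sigma = 0, n_samples = 1, seed = 2),
                      objective = objective_config(K = 1, loss_assignment = "cce",
                                                   drop_prob = 0))
  cv <- cross_validate(ds, gspec, dspecs, cfg, k = 3)
  expect_length(cv$reports, 3)
  for (r in cv$reports) expect_equal(r$n_images[r$class == "macro"], 2)
  f1s <- vapply(cv$reports, function(r) r$f1[r$class == "macro"], numeric(1))
  expect_equal(cv$summary$mean[cv$summary$metric == "f1"], mean(f1s))
  expect_equal(cv$summary$sd[cv$summary$metric == "f1"], sd(f1s))
})

test_that("generator auxiliary loss decreases over the first training epochs", {
  run <- desk_run()
  h <- run$fit$history
  em <- vapply(split(h$gen_aux, h$epoch), mean, numeric(1))
  expect_true(all(diff(em[1:3]) < 0))
})

test_that("no validation sample ever enters a parameter update", {
  run <- desk_run()
  trained_ids <- unlist(strsplit(run$fit$history$sample_id, ","))
  val_ids <- vapply(run$val_set, function(s) s$sample_id, character(1))
  train_ids <- vapply(run$train_set, function(s) s$sample_id, character(1))
  expect_length(intersect(trained_ids, setdiff(val_ids, train_ids)), 0)
  expect_setequal(unique(trained_ids), train_ids)
})

test_that("training histories log every stochastic control decision", {
  run <- desk_run()
  h <- run$fit$history
  expect_true(all(h$mode %in% c("sum", "average", "maximum")))
  expect_true(all(nchar(h$active) == 3))
  expect_true(all(vapply(strsplit(h$active, ""), function(a) any(a == "1"),
                         logical(1))))
  expect_equal(nrow(h), 5 * 200)
})
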