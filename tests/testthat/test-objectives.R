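test_that("dice loss reproduces the hand-derived cases", {
  H <- 4; W <- 4
  t <- matrix(0L, H, W); t[1:2, 1:2] <- 1L
  t1h <- begas:::as_onehot(t, 2)
  expect_equal(dice_loss(t1h, t1h), 0, tolerance = 1e-5)
  disj <- matrix(0L, H, W); disj[3:4, 3:4] <- 1L
  expect_equal(dice_loss(begas:::as_onehot(disj, 2), t1h), 1, tolerance = 1e-5)
  # |A| = |B| = 4, overlap 2 -> 1 - 2*2/8 = 0.5
  half <- matrix(0L, H, W); half[1:2, 2:3] <- 1L
  expect_equal(dice_loss(begas:::as_onehot(half, 2), t1h), 0.5, tolerance = 1e-5)
  bad <- begas:::as_onehot(t, 2) * 2
  expect_error(dice_loss(bad, t1h), "simplex")
})

test_that("mae and cce losses match their closed forms and the oracle", {
  t <- matrix(sample(0:2, 64, TRUE), 8, 8)
  t1h <- begas:::as_onehot(t, 3)
  expect_equal(mae_loss(t1h, t1h), 0)
  # true-class probability 0.5 everywhere -> cce = ln 2
  p <- t1h * 0.5 + (1 - t1h) * 0.25
  expect_equal(as.numeric(cce_loss(p, t1h)), log(2), tolerance = 1e-12)
  maps <- random_prob_maps(1, H = 8, W = 8, C = 3, seed = 3)[[1]]
  expect_equal(as.numeric(cce_loss(maps, t1h)), oracle_cce(maps, t1h),
               tolerance = 1e-10)
})

test_that("adversarial value follows the minimax closed forms", {
  # all scores 0.5, lambda 1 -> -2 ln 2
  s <- matrix(0.5, 4, 4)
  expect_equal(adversarial_value(s, s, 1), -2 * log(2), tolerance = 1e-12)
  # perfect discriminator -> V -> 0 from below
  eps <- 1e-9
  v <- adversarial_value(matrix(1 - eps, 2, 2), matrix(eps, 2, 2), 1)
  expect_lt(v, 0)
  expect_gt(v, -1e-8)
  # lambda = 0 annihilates the fake term
  expect_equal(adversarial_value(s, matrix(0.9, 2, 2), 0), mean(log(s)))
  expect_error(adversarial_value(matrix(1.2, 2, 2), s), "open interval")
})

test_that("feedback aggregation honours mode and active mask", {
  expect_equal(aggregate_feedback(c(1, 2, 3), "sum"), 6)
  expect_equal(aggregate_feedback(c(1, 2, 3), "average"), 2)
  expect_equal(aggregate_feedback(c(1, 2, 3), "maximum",
                                  active_mask = c(TRUE, FALSE, TRUE)), 3)
  expect_error(aggregate_feedback(c(1, 2), "sum", active_mask = c(FALSE, FALSE)),
               "at least one")
  # exact identity: sum = K * average when all active (K a power of two so
  # the division is exact in floating point)
  v <- withr::with_seed(3, rnorm(4))
  expect_identical(aggregate_feedback(v, "sum"), 4 * aggregate_feedback(v, "average"))
  v5 <- withr::with_seed(4, rnorm(5))
  expect_equal(aggregate_feedback(v5, "sum"), 5 * aggregate_feedback(v5, "average"),
               tolerance = 1e-15)
})

test_that("dice gradient agrees with finite differences", {
  withr::with_seed(8, {
    e <- array(rexp(3 * 3 * 2), dim = c(3, 3, 2))
    s <- apply(e, c(1, 2), sum)
    p <- e / array(rep(s, 2), dim = c(3, 3, 2))
    t1h <- begas:::as_onehot(matrix(sample(0:1, 9, TRUE), 3, 3), 2)
    g <- begas:::dice_loss_grad(p, t1h)
    eps <- 1e-6
    for (i in sample(length(p), 6)) {
      p1 <- p; p1[i] <- p1[i] + eps
      p2 <- p; p2[i] <- p2[i] - eps
      num <- (begas:::dice_raw(p1, t1h) - begas:::dice_raw(p2, t1h)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  })
})

test_that("generator loss reduces to the conditional-GAN objective at K = 1", {
  ds <- generate_segmentation_dataset(phantom_preset("desk"), 2, seed = 4)
  gspec <- generator_spec(n_classes = 3, base_channels = 4, noise_dim = 4)
  gen <- build_generator(gspec, seed = 1)
  d1 <- build_discriminator(discriminator_spec(16, 4, "cce"), 1, 3, seed = 2)
  cfg1 <- objective_config(K = 1, loss_assignment = "cce", drop_prob = 0)
  la <- generator_loss(ds, gen, list(d1), cfg1, mode = "sum")
  lb <- generator_loss(ds, gen, list(d1), cfg1, mode = "maximum")
  expect_identical(la$total, lb$total) # mode irrelevant for K = 1
  expect_equal(nrow(la$breakdown), 1)
  # doubling lambda_k for one k changes only that adversarial contribution
  d2 <- build_discriminator(discriminator_spec(16, 4, "dice"), 1, 3, seed = 3)
  cfg2 <- objective_config(K = 2, lambda_k = c(1, 1),
                           loss_assignment = c("cce", "dice"), drop_prob = 0)
  cfg2b <- objective_config(K = 2, lambda_k = c(1, 2),
                            loss_assignment = c("cce", "dice"), drop_prob = 0)
  b1 <- generator_loss(ds, gen, list(d1, d2), cfg2, mode = "sum")$breakdown
  b2 <- generator_loss(ds, gen, list(d1, d2), cfg2b, mode = "sum")$breakdown
  expect_identical(b1$adversarial[1], b2$adversarial[1])
  expect_equal(b2$adversarial[2], 2 * b1$adversarial[2], tolerance = 1e-12)
  expect_identical(b1$auxiliary, b2$auxiliary)
})

test_that("a perfect prediction drives the auxiliary losses to zero", {
  ds <- generate_segmentation_dataset(phantom_preset("desk"), 1, seed = 6)
  gspec <- generator_spec(n_classes = 3, base_channels = 4, noise_dim = 4)
  gen <- build_generator(gspec, seed = 1)
  # evaluate the losses directly at the one-hot truth
  y1h <- begas:::as_onehot(ds[[1]]$mask, 3)
  p <- pmin(pmax(y1h, 1e-7), 1)
  p <- p / array(rep(apply(p, c(1, 2), sum), 3), dim = dim(p))
  expect_lt(as.numeric(cce_loss(p, y1h)), 1e-5)
  expect_lt(dice_loss(p, y1h), 1e-3)
  expect_lt(mae_loss(p, y1h), 1e-5)
})
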