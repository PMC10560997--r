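test_that("predictive mean matches the brute-force oracle and its edge cases", {
  one_pixel <- function(v) array(v, dim = c(1, 1, length(v)))
  m <- predictive_mean(list(one_pixel(c(1, 0)), one_pixel(c(0, 1))))
  expect_equal(as.vector(m), c(0.5, 0.5))
  maps <- random_prob_maps(5, seed = 11)
  expect_identical(predictive_mean(rep(maps[1], 4))[], maps[[1]][]) # idempotent
  expect_equal(predictive_mean(maps), oracle_elementwise_mean(maps),
               tolerance = 1e-12)
  expect_error(predictive_mean(list()), "at least one")
})

test_that("second moment reproduces the worked example and the oracle", {
  one_pixel <- function(v) array(v, dim = c(1, 1, length(v)))
  freq <- class_frequency_spec(c(0.5, 0.5))
  # two samples (1,0), (0,1): u = diag(2,2) + diag(.5,.5) - [[.25,.25],[.25,.25]]
  u <- predictive_uncertainty(list(one_pixel(c(1, 0)), one_pixel(c(0, 1))), freq)
  expect_equal(matrix(u[1, 1, , ], 2, 2),
               matrix(c(2.25, -0.25, -0.25, 2.25), 2, 2))
  # zero spread: all samples identical -> u = diag(1/tau) exactly
  s <- one_pixel(c(0.3, 0.7))
  u0 <- predictive_uncertainty(list(s, s, s), freq)
  expect_identical(matrix(u0[1, 1, , ], 2, 2), diag(2, 2))
  # random maps vs. the per-pixel oracle, and symmetry to 1e-12
  maps <- random_prob_maps(4, H = 3, W = 3, C = 3, seed = 5)
  freq3 <- class_frequency_spec(c(0.7, 0.2, 0.1))
  u3 <- predictive_uncertainty(maps, freq3)
  for (i in 1:3) for (j in 1:3) {
    pix <- lapply(maps, function(m) m[i, j, ])
    expect_equal(matrix(u3[i, j, , ], 3, 3), oracle_u_pixel(pix, freq3$tau),
                 tolerance = 1e-12)
    expect_equal(u3[i, j, , ], t(u3[i, j, , ]), tolerance = 1e-12)
  }
  # diagonal-only agrees with the full diagonal
  ud <- predictive_uncertainty(maps, freq3, diagonal_only = TRUE)
  expect_equal(ud[2, 2, ], diag(matrix(u3[2, 2, , ], 3, 3)), tolerance = 1e-12)
  expect_error(class_frequency_spec(c(0, 1)), "positive")
})

test_that("ood score is zero for certain predictions and linear in a constant field", {
  one_pixel <- function(v) array(v, dim = c(1, 1, length(v)))
  freq <- class_frequency_spec(c(0.5, 0.5))
  s <- array(rep(c(1, 0), each = 16), dim = c(4, 4, 2))
  mom <- predictive_moments(list(s, s), freq)
  expect_equal(mom$ood_score, 0, tolerance = 1e-12)
  expect_equal(ood_score(mom), 0, tolerance = 1e-12)
  # constant per-pixel disagreement v -> score v under mean reduction
  a <- array(rep(c(1, 0), each = 16), dim = c(4, 4, 2))
  b <- array(rep(c(0, 1), each = 16), dim = c(4, 4, 2))
  mom2 <- predictive_moments(list(a, b), freq)
  # each class variance = 0.25, trace = 0.5 at every pixel
  expect_equal(mom2$ood_score, 0.5, tolerance = 1e-12)
  expect_equal(ood_score(mom2, reduction = "max"), 0.5, tolerance = 1e-12)
  expect_error(ood_score(mom2, reduction = "quantile"), "`q`")
})

test_that("mc_predict is deterministic and degenerates to the plain forward pass", {
  spec <- generator_spec(n_classes = 3, base_channels = 4, noise_dim = 4)
  gen <- build_generator(spec, seed = 2)
  x <- matrix(runif(32 * 32), 32, 32)
  cfg1 <- dropout_config(sigma = 0, n_samples = 1, seed = 6)
  maps <- mc_predict(gen, x, cfg1)
  expect_length(maps, 1)
  z <- withr::with_seed(substream_seed(6, "z", 0), rnorm(4))
  expect_identical(maps[[1]], predict(gen, x, z = z))
  cfg5 <- dropout_config(sigma = 0.2, n_samples = 5, seed = 6)
  m1 <- mc_predict(gen, x, cfg5)
  m2 <- mc_predict(gen, x, cfg5)
  expect_identical(m1, m2)
  for (m in m1) {
    expect_equal(apply(m, c(1, 2), sum), matrix(1, 32, 32), tolerance = 1e-5)
  }
})

test_that("MC variance matches the closed form for a linear toy model", {
  # y = theta*delta*x, delta ~ N(1, sigma): Var(y) = sigma^2 theta^2 x^2
  theta <- 2; x <- 1.5; sigma <- 0.3; N <- 1e5
  draws <- withr::with_seed(substream_seed(123, "dropout", 0),
                            theta * rnorm(N, 1, sigma) * x)
  v_mc <- mean(draws^2) - mean(draws)^2
  v_exact <- sigma^2 * theta^2 * x^2
  expect_lt(abs(v_mc - v_exact) / v_exact, 0.05)
})

test_that("total predictive variance is non-decreasing in sigma on a frozen net", {
  spec <- generator_spec(n_classes = 3, base_channels = 4, noise_dim = 4)
  gen <- build_generator(spec, seed = 3)
  x <- matrix(runif(32 * 32), 32, 32)
  v <- vapply(c(0, 0.1, 0.3), function(s) {
    cfg <- dropout_config(sigma = s, n_samples = 8, seed = 4)
    ood_score(mc_predict(gen, x, cfg))
  }, numeric(1))
  expect_true(all(diff(v) >= 0))
  expect_equal(v[1], 0, tolerance = 1e-12)
})

test_that("tail classes carry higher uncertainty than the background after training", {
  run <- desk_run()
  cu <- class_uncertainty(run$fit, run$val_set[1:20])
  u_bg <- cu$mean_u[cu$class == "background"]
  u_lesion <- cu$mean_u[cu$class == "lesion"]
  expect_gt(u_lesion, u_bg)
})
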