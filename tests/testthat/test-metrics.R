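test_that("confusion scores reproduce the hand-derived cases", {
  t <- matrix(0L, 4, 4); t[1, 1:4] <- 1L
  expect_equal(confusion_scores(t, t, 1)[, c("precision", "recall", "f1")],
               tibble::tibble(precision = 1, recall = 1, f1 = 1))
  # TP = 3, FP = 1, FN = 1 -> all three 0.75
  p <- matrix(0L, 4, 4); p[1, 1:3] <- 1L; p[2, 1] <- 1L
  cs <- confusion_scores(p, t, 1)
  expect_equal(c(cs$precision, cs$recall, cs$f1), c(0.75, 0.75, 0.75))
  # no predicted positives while positives exist: flagged zeros
  none <- matrix(0L, 4, 4)
  cs2 <- confusion_scores(none, t, 1)
  expect_equal(c(cs2$precision, cs2$recall), c(0, 0))
  expect_true(cs2$degenerate)
  # class absent from both masks: undefined, excluded from averages
  expect_true(confusion_scores(none, none, 1)$undefined)
})

test_that("assd matches hand values and the all-pairs brute-force oracle", {
  m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
  expect_equal(assd(m, m), 0)
  # two single pixels 3 apart on one row
  a <- matrix(0L, 8, 8); a[4, 2] <- 1L
  b <- matrix(0L, 8, 8); b[4, 5] <- 1L
  expect_equal(assd(a, b), 3)
  expect_identical(assd(a, b), assd(b, a)) # exact symmetry
  # square vs. shifted square and random masks vs. the oracle
  sq <- matrix(0L, 32, 32); sq[10:20, 10:20] <- 1L
  sh <- matrix(0L, 32, 32); sh[11:21, 10:20] <- 1L
  expect_equal(assd(sq, sh), oracle_assd(sq, sh), tolerance = 1e-9)
  withr::with_seed(17, {
    for (rep in 1:3) {
      ra <- matrix(0L, 32, 32); rb <- matrix(0L, 32, 32)
      ra[sample(1024, 60)] <- 1L; rb[sample(1024, 60)] <- 1L
      expect_equal(assd(ra, rb), oracle_assd(ra, rb), tolerance = 1e-9)
      expect_identical(assd(ra, rb), assd(rb, ra))
    }
  })
  empty <- matrix(0L, 8, 8)
  expect_true(is.infinite(assd(empty, m)))
})

test_that("ece reproduces the single-bin case and the binning oracle", {
  expect_equal(expected_calibration_error(rep(1, 10), rep(TRUE, 10)), 0)
  # 10 predictions at confidence 0.8, 6 correct -> |0.8 - 0.6| = 0.2
  expect_equal(expected_calibration_error(rep(0.8, 10),
                                          c(rep(TRUE, 6), rep(FALSE, 4))),
               0.2, tolerance = 1e-12)
  withr::with_seed(23, {
    conf <- runif(500); correct <- runif(500) < conf
    expect_equal(expected_calibration_error(conf, correct, 10),
                 oracle_ece(conf, correct, 10), tolerance = 1e-12)
  })
  # calibrated-by-construction data scores zero
  conf <- rep(c(0.25, 0.75), each = 4)
  correct <- c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(expected_calibration_error(conf, correct, 4), 0, tolerance = 1e-12)
  expect_error(expected_calibration_error(numeric(0), logical(0)), "non-empty")
})

test_that("nll matches its closed forms and equals cce by definition", {
  t <- matrix(sample(0:1, 16, TRUE), 4, 4)
  t1h <- begas:::as_onehot(t, 2)
  expect_equal(negative_log_likelihood(t1h, t), 0, tolerance = 1e-10)
  p <- t1h * 0.5 + (1 - t1h) * 0.5
  expect_equal(negative_log_likelihood(p, t), log(2), tolerance = 1e-12)
  maps <- random_prob_maps(1, 4, 4, 2, seed = 9)[[1]]
  expect_identical(negative_log_likelihood(maps, t), as.numeric(cce_loss(maps, t)))
})

test_that("auroc uses the Mann-Whitney ties convention and is rank-invariant", {
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auroc(rep(0.7, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  # worked example: pairs (pos > neg) = 3 of 4 -> 0.75
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  withr::with_seed(31, {
    sc <- c(rnorm(20), rnorm(15, 1)); lab <- rep(c(0, 1), c(20, 15))
    a <- auroc(sc, lab)
    expect_equal(a, oracle_auroc_pairs(sc, lab), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(auroc(exp(sc), lab), a, tolerance = 1e-12)
    expect_equal(auroc(3 * sc - 10, lab), a, tolerance = 1e-12)
    # independent reference implementation
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(a, as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))),
                   tolerance = 1e-12)
    }
  })
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  r <- paired_t_test(c(2, 3, 4), c(1, 1, 1)) # differences (1,2,3)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  ref <- t.test(c(2, 3, 4), c(1, 1, 1), paired = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_true(same$degenerate)
})
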