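test_that("segmentation generation is deterministic, stateless and order-invariant", {
  spec <- phantom_preset("desk")
  a <- generate_segmentation_dataset(spec, 5, seed = 3)
  set.seed(999) # unrelated RNG activity must not matter
  b <- generate_segmentation_dataset(spec, 5, seed = 3)
  expect_identical(a, b)
  # extending the dataset must not reshuffle earlier images
  c10 <- generate_segmentation_dataset(spec, 10, seed = 3)
  expect_identical(a[1:5], c10[1:5])
  expect_length(generate_segmentation_dataset(spec, 0, seed = 1), 0)
  expect_true(all(vapply(a, function(s) any(s$mask == 0), logical(1))))
})

test_that("pooled class fractions hit the targets", {
  # lits-like extreme tail: 1:1400 lesion-to-background, 20% relative band
  lits <- phantom_preset("lits-like")
  ds <- generate_segmentation_dataset(lits, 200, seed = 7)
  fr <- pooled_class_fractions(ds)
  ratio <- fr$pixels[3] / fr$pixels[1]
  expect_gt(ratio, (1 / 1400) * 0.8)
  expect_lt(ratio, (1 / 1400) * 1.2)
  # convergence property: desk preset at n = 500, all classes within 10%
  desk <- phantom_preset("desk")
  fr5 <- pooled_class_fractions(generate_segmentation_dataset(desk, 500, seed = 21))
  rel <- abs(fr5$fraction - desk$target_ratios) / desk$target_ratios
  expect_true(all(rel < 0.10))
})

test_that("invalid and infeasible specs are rejected with the class named", {
  expect_error(imbalance_spec(c("bg", "fg"), c(0.3, 0.7)), "largest")
  expect_error(imbalance_spec(c("bg", "fg"), c(0.5, 0.4)), "sum to 1")
  expect_error(imbalance_spec(c("bg", "fg"), c(0.9, 0.1),
                              lesion_size_range = c(3, 80)), "lesion_size_range")
  # tail class demanding more than 3 blobs per image at the requested size
  bad <- imbalance_spec(c("background", "organ", "lesion"),
                        c(0.7, 0.1, 0.2), image_size = c(64, 64),
                        lesion_size_range = c(2, 3), tail_classes = "lesion")
  expect_error(generate_segmentation_dataset(bad, 1, seed = 1), "lesion")
})

test_that("classification generator honours counts, ratio and degeneracy", {
  ds <- generate_classification_dataset(60, 2, seed = 5, image_size = c(32, 32))
  labels <- vapply(ds, function(s) s$label, integer(1))
  expect_equal(sum(labels == 0) / sum(labels == 1), 30) # 1:30 by construction
  expect_identical(labels,
                   vapply(generate_classification_dataset(60, 2, seed = 5),
                          function(s) s$label, integer(1)))
  expect_warning(d0 <- generate_classification_dataset(5, 0, seed = 1),
                 "single class")
  expect_true(isTRUE(attr(d0, "degenerate_single_class")))
  expect_error(generate_classification_dataset(-1, 5), ">= 0")
})

test_that("domain shift preserves labels, tags ood, and identity is a no-op", {
  ds <- generate_segmentation_dataset(phantom_preset("desk"), 4, seed = 2)
  expect_identical(apply_domain_shift(ds, shift_spec(), seed = 1), ds)
  shifted <- apply_domain_shift(ds, default_ood_shift(), seed = 1)
  expect_true(all(vapply(shifted, function(s) s$domain_tag == "ood", logical(1))))
  for (i in seq_along(ds)) expect_identical(shifted[[i]]$mask, ds[[i]]$mask)
  expect_error(apply_domain_shift(list(), default_ood_shift()), "non-empty")
})

test_that("pure intensity offset raises mean intensity by the offset", {
  flat <- list(image_sample(matrix(0.4, 16, 16), mask = matrix(0L, 16, 16),
                            sample_id = "flat"))
  out <- apply_domain_shift(flat, shift_spec(intensity_offset = 0.3), seed = 1)
  expect_equal(mean(out[[1]]$image) - mean(flat[[1]]$image), 0.3, tolerance = 1e-12)
  # heavy clipping is detected
  expect_warning(
    apply_domain_shift(list(image_sample(matrix(0.9, 8, 8), sample_id = "hot")),
                       shift_spec(intensity_offset = 0.5), seed = 1),
    "clipped")
})
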