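test_that("datasets round-trip through PNG + manifest exactly enough", {
  ds <- generate_segmentation_dataset(phantom_preset("desk", c(32, 32)), 3, seed = 5)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, force = TRUE)
  expect_error(write_dataset(ds, dir), "exists")
  back <- read_dataset(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, ds[[i]]$mask) # labels are bit-exact
    expect_lt(max(abs(back[[i]]$image - ds[[i]]$image)), 1 / 255)
    expect_identical(back[[i]]$sample_id, ds[[i]]$sample_id)
  }
  # same data written twice gives identical file hashes
  dir2 <- withr::local_tempdir()
  write_dataset(ds, dir2, force = TRUE)
  h1 <- tools::md5sum(sort(list.files(dir, full.names = TRUE)))
  h2 <- tools::md5sum(sort(list.files(dir2, full.names = TRUE)))
  expect_identical(unname(h1), unname(h2))
})

test_that("run configurations survive a YAML round trip", {
  rc <- run_config(task = "segmentation", seed = 42, n_images = 20,
                   imbalance = phantom_preset("lits-like"),
                   dropout = dropout_config(sigma = 0.2, n_samples = 4, seed = 42),
                   objective = objective_config(K = 2, lambda_k = c(1, 0.5),
                                                loss_assignment = c("mae", "dice"),
                                                drop_prob = 0.2),
                   epochs = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  save_run_config(rc, path)
  back <- load_run_config(path)
  expect_equal(back$seed, rc$seed)
  expect_equal(back$imbalance$target_ratios, rc$imbalance$target_ratios)
  expect_equal(back$train$dropout$sigma, rc$train$dropout$sigma)
  expect_equal(back$train$objective$lambda_k, rc$train$objective$lambda_k)
  expect_equal(back$train$objective$loss_assignment,
               rc$train$objective$loss_assignment)
  expect_equal(back$train$epochs, rc$train$epochs)
  expect_equal(vapply(back$discriminators, function(d) d$loss_type, character(1)),
               vapply(rc$discriminators, function(d) d$loss_type, character(1)))
})

test_that("checkpoints restore a model that predicts identically", {
  ds <- generate_segmentation_dataset(phantom_preset("desk", c(32, 32)), 4, seed = 8)
  gspec <- generator_spec(n_classes = 3, base_channels = 2, noise_dim = 2)
  cfg <- train_config(epochs = 1, seed = 6,
                      dropout = dropout_config(sigma = 0, n_samples = 1, seed = 6),
                      objective = objective_config(K = 1, loss_assignment = "mae",
                                                   drop_prob = 0))
  fit <- train(ds, NULL, gspec, list(discriminator_spec(16, 2, "mae")), cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  x <- ds[[1]]$image
  expect_identical(predict(back$generator, x, seed = 1),
                   predict(fit$generator, x, seed = 1))
  expect_error(load_checkpoint(withr::local_tempfile(fileext = ".rds")),
               "not found")
})

test_that("classification datasets reduce to constant-mask segmentation tasks", {
  cls <- generate_classification_dataset(4, 2, seed = 3, image_size = c(32, 32))
  seg <- as_segmentation_task(cls)
  expect_identical(attr(seg, "task"), "classification")
  for (i in seq_along(seg)) {
    expect_true(all(seg[[i]]$mask == cls[[i]]$label))
    expect_identical(dim(seg[[i]]$mask), dim(seg[[i]]$image)[1:2])
  }
})

test_that("cli verbs simulate, train, evaluate and score ood end to end", {
  dir <- withr::local_tempdir()
  data_dir <- file.path(dir, "data")
  suppressMessages(cli_simulate(list(preset = "desk", n = 6, seed = 4,
                                     out = data_dir)))
  expect_true(file.exists(file.path(data_dir, "manifest.csv")))
  expect_length(list.files(data_dir, pattern = "_img\\.png$"), 6)
  expect_error(cli_simulate(list(preset = "desk", n = 2, seed = 4,
                                 out = data_dir)), "exists")
  ood_dir <- file.path(dir, "ood")
  suppressMessages(cli_simulate(list(preset = "desk", n = 4, seed = 4,
                                     out = ood_dir, ood_shift = TRUE)))
  mf <- read.csv(file.path(ood_dir, "manifest.csv"))
  expect_true(all(mf$domain_tag == "ood"))
  run_dir <- file.path(dir, "run")
  fit <- suppressMessages(
    cli_train(list(data = data_dir, out = run_dir, seed = 4, epochs = 1,
                   K = 1, sigma = 0, n_mc = 1)))
  expect_true(file.exists(file.path(run_dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(run_dir, "config.yaml")))
  expect_true(file.exists(file.path(run_dir, "history.csv")))
  # rerunning from the snapshot config reproduces the run bit-for-bit
  run_dir2 <- file.path(dir, "run2")
  suppressMessages(
    cli_train(list(data = data_dir, out = run_dir2, seed = 4,
                   config = file.path(run_dir, "config.yaml"))))
  expect_identical(unname(tools::md5sum(file.path(run_dir, "history.csv"))),
                   unname(tools::md5sum(file.path(run_dir2, "history.csv"))))
  rep <- suppressMessages(
    cli_evaluate(list(checkpoint = file.path(run_dir, "checkpoint.rds"),
                      data = data_dir,
                      out = file.path(dir, "eval.csv"), n_mc = 1)))
  expect_true("macro" %in% rep$class)
  pm <- cli_predict(list(checkpoint = file.path(run_dir, "checkpoint.rds"),
                         data = data_dir, out = file.path(dir, "preds"),
                         n_mc = 1))
  expect_equal(nrow(pm), 6)
  expect_length(list.files(file.path(dir, "preds"), pattern = "_pred\\.png$"), 6)
  sc <- suppressMessages(
    cli_ood(list(checkpoint = file.path(run_dir, "checkpoint.rds"),
                 data = ood_dir, out = file.path(dir, "scores.csv"))))
  expect_equal(nrow(sc), 4)
  expect_true(file.exists(file.path(dir, "scores.csv")))
  expect_error(cli_ood(list(checkpoint = file.path(dir, "nope.rds"),
                            data = ood_dir)), "not found")
})
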