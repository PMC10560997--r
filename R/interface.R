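#' Write a phantom dataset to disk
#'
#' Images are written as 8-bit grayscale (or RGB) PNGs, masks as
#' single-channel integer PNGs (pixel value = class label; no palette), plus
#' a CSV manifest (`sample_id`, paths, label, domain_tag).
#'
#' @param samples a `phantom_dataset` (list of [image_sample]).
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory?
#' @return Invisibly, the manifest tibble.
#' @export
write_dataset <- function(samples, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    abort(sprintf("output directory '%s' exists and is not empty (use force)", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    img_path <- file.path(dir, paste0(s$sample_id, "_img.png"))
    png::writePNG(s$image, img_path)
    mask_path <- NA_character_
    if (!is.null(s$mask)) {
      mask_path <- file.path(dir, paste0(s$sample_id, "_mask.png"))
      png::writePNG(s$mask / 255, mask_path)
    }
    tibble(sample_id = s$sample_id,
           image = basename(img_path),
           mask = if (is.na(mask_path)) NA_character_ else basename(mask_path),
           label = if (is.null(s$label)) NA_integer_ else s$label,
           domain_tag = s$domain_tag)
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom dataset from a manifest directory
#'
#' Masks must be single-channel integer PNGs (pixel value = label); palette
#' or multi-channel mask PNGs are rejected with guidance.
#'
#' @param dir directory containing `manifest.csv` written by [write_dataset()].
#' @return A `phantom_dataset` list of [image_sample] objects.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort(sprintf("no manifest.csv in '%s'", dir))
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    img <- png::readPNG(file.path(dir, r$image))
    mask <- NULL
    if (!is.na(r$mask) && nzchar(r$mask)) {
      m <- png::readPNG(file.path(dir, r$mask))
      if (length(dim(m)) == 3) {
        abort("mask PNGs must be single-channel integer-label images, not palette/RGB")
      }
      mask <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
    }
    image_sample(img, mask = mask,
                 label = if (is.na(r$label)) NULL else as.integer(r$label),
                 sample_id = r$sample_id,
                 domain_tag = if (identical(r$domain_tag, "ood")) "ood" else "in_distribution")
  })
  task <- if (all(is.na(manifest$label))) "segmentation" else "classification"
  structure(samples, class = c("phantom_dataset", "list"), task = task)
}

#' Export a stack of maps as NIfTI
#'
#' Stacks 2D arrays (e.g. uncertainty maps) into a pseudo-volume and writes a
#' `.nii.gz` via RNifti when available.
#'
#' @param maps list of H x W numeric matrices.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing voxel spacing `c(row, col, slice)`.
#' @return The path, invisibly.
#' @export
export_nifti <- function(maps, path, spacing = c(1, 1, 1)) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("NIfTI export requires the RNifti package")
  }
  vol <- array(unlist(maps), dim = c(dim(maps[[1]]), length(maps)))
  img <- RNifti::asNifti(vol, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Save / load a parameter checkpoint
#'
#' A single-file container (RDS) with a `version` field, the architecture
#' specs, parameters, optimizer state and class frequencies, sufficient to
#' resume prediction.
#'
#' @param fit a `begas_fit`.
#' @param path output file.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: a
#'   `begas_fit` (without training history).
#' @export
save_checkpoint <- function(fit, path) {
  obj <- list(version = 1L,
              generator_spec = fit$generator$spec,
              generator_params = fit$generator$params,
              discriminators = lapply(fit$discriminators, function(d)
                list(spec = d$spec, params = d$params,
                     image_channels = d$image_channels, n_classes = d$n_classes)),
              freq = fit$freq, cfg = fit$cfg, class_names = fit$class_names)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort(sprintf("checkpoint '%s' not found", path))
  obj <- readRDS(path)
  if (is.null(obj$version) || obj$version != 1L) {
    abort("unsupported checkpoint version (expected version 1)")
  }
  gen <- structure(list(spec = obj$generator_spec, params = obj$generator_params,
                        kernel = 3L), class = "hourglass_generator")
  discs <- lapply(obj$discriminators, function(d)
    structure(list(spec = d$spec, params = d$params,
                   image_channels = d$image_channels, n_classes = d$n_classes),
              class = "patch_discriminator"))
  structure(list(generator = gen, discriminators = discs, history = NULL,
                 freq = obj$freq, cfg = obj$cfg, class_names = obj$class_names),
            class = "begas_fit")
}

spec_to_list <- function(x) {
  out <- unclass(x)
  out[] <- lapply(out, function(v) if (inherits(v, "tbl_df")) as.data.frame(v) else v)
  out
}

#' Save / load a run configuration
#'
#' Serialises every tunable of a run (task, imbalance spec, shift spec,
#' dropout, objective and training configs) to a single YAML file; reloading
#' a saved configuration reproduces the run given the same seed.
#'
#' @param config a named list as assembled by [run_config()].
#' @param path YAML file path.
#' @return `save_run_config`: the path, invisibly. `load_run_config`: the
#'   reconstructed config list.
#' @export
save_run_config <- function(config, path) {
  ser <- list(
    task = config$task,
    seed = config$seed,
    n_images = config$n_images,
    imbalance = spec_to_list(config$imbalance),
    shift = spec_to_list(config$shift),
    dropout = spec_to_list(config$train$dropout),
    objective = {
      ob <- spec_to_list(config$train$objective)
      # yaml drops names on atomic vectors; keep these as maps
      ob$mode_probs <- as.list(ob$mode_probs)
      ob$aux_weights <- as.list(ob$aux_weights)
      ob
    },
    train = spec_to_list(config$train[setdiff(names(config$train),
                                              c("dropout", "objective"))]),
    generator = spec_to_list(config$generator),
    discriminators = lapply(config$discriminators, spec_to_list)
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  imb <- y$imbalance
  train_extra <- y$train
  cfg <- run_config(
    task = y$task, seed = y$seed, n_images = y$n_images,
    imbalance = imbalance_spec(
      class_names = imb$class_names,
      target_ratios = unlist(imb$target_ratios),
      image_size = unlist(imb$image_size),
      intensity_model = as_tibble(as.data.frame(imb$intensity_model)),
      lesion_size_range = unlist(imb$lesion_size_range),
      tail_classes = unlist(imb$tail_classes) %||% character()),
    shift = do.call(shift_spec, y$shift),
    dropout = do.call(dropout_config, y$dropout),
    objective = do.call(objective_config, c(
      y$objective[c("K", "lambda_k", "loss_assignment", "aggregation_mode",
                    "drop_prob", "adversarial")],
      list(mode_probs = unlist(y$objective$mode_probs),
           aux_weights = unlist(y$objective$aux_weights)))),
    epochs = train_extra$epochs,
    generator = do.call(generator_spec,
                        y$generator[c("n_classes", "stacks", "base_channels",
                                      "input_channels", "noise_dim")]),
    discriminators = lapply(y$discriminators, function(d)
      discriminator_spec(d$patch_receptive_field, d$base_channels, d$loss_type))
  )
  for (fld in c("learning_rate", "batch_size", "weight_decay", "adam_beta1",
                "adam_beta2", "dropout_at_train", "lr_schedule", "lr_final")) {
    if (!is.null(train_extra[[fld]])) cfg$train[[fld]] <- train_extra[[fld]]
  }
  cfg
}

#' Reduce a classification dataset to the segmentation machinery
#'
#' Image-level labels are broadcast to constant per-pixel label maps, so the
#' conditional adversarial framework, Monte-Carlo moments and calibration
#' metrics apply unchanged; the image-level class probability of a trained
#' model is the spatial mean of its predictive-mean map.
#'
#' @param samples classification `phantom_dataset` (samples with `label`).
#' @return The same dataset with per-sample constant masks added.
#' @export
as_segmentation_task <- function(samples) {
  out <- lapply(samples, function(s) {
    if (is.null(s$label)) return(s)
    d <- dim(s$image)
    image_sample(s$image, mask = matrix(as.integer(s$label), d[1], d[2]),
                 label = s$label, sample_id = s$sample_id,
                 domain_tag = s$domain_tag)
  })
  attributes(out) <- attributes(samples)
  out
}

#' Assemble a full run configuration
#'
#' @param task `"segmentation"`, `"classification"` or `"ood"`.
#' @param seed master seed.
#' @param n_images training-set size for simulation.
#' @param imbalance an [imbalance_spec].
#' @param shift a [shift_spec].
#' @param dropout a [dropout_config].
#' @param objective an [objective_config].
#' @param epochs training epochs.
#' @param generator a [generator_spec] (defaults to one matching `imbalance`).
#' @param discriminators list of [discriminator_spec] (defaults to K specs
#'   with mae/cce/dice assignments).
#' @return A named config list of class `run_config`.
#' @export
run_config <- function(task = c("segmentation", "classification", "ood"),
                       seed = 0, n_images = 200,
                       imbalance = phantom_preset("desk"),
                       shift = default_ood_shift(),
                       dropout = dropout_config(),
                       objective = objective_config(),
                       epochs = 5,
                       generator = NULL, discriminators = NULL) {
  task <- match.arg(task)
  C <- length(imbalance$class_names)
  generator <- generator %||% generator_spec(n_classes = C)
  if (is.null(discriminators)) {
    losses <- rep_len(objective$loss_assignment, objective$K)
    discriminators <- lapply(losses, function(l) discriminator_spec(loss_type = l))
  }
  train <- train_config(epochs = epochs, seed = seed, dropout = dropout,
                        objective = objective)
  structure(list(task = task, seed = seed, n_images = n_images,
                 imbalance = imbalance, shift = shift, train = train,
                 generator = generator, discriminators = discriminators),
            class = "run_config")
}
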