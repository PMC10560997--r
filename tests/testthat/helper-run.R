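# Memoised desk-scale end-to-end run shared by the training, uncertainty and
# acceptance tests: 200 training / 50 validation 64x64 phantoms with a pooled
# lesion:background ratio near 1:100, K = 3 discriminators (mae/cce/dice),
# N = 5 Monte-Carlo samples, 5 epochs, seed 13.
.run_cache <- new.env(parent = emptyenv())

desk_run <- function() {
  if (!is.null(.run_cache$fit)) return(as.list(.run_cache))
  spec <- phantom_preset("desk")
  train_set <- generate_segmentation_dataset(spec, 200, seed = 7)
  val_set <- generate_segmentation_dataset(spec, 50, seed = 1007)
  ood_set <- apply_domain_shift(val_set, default_ood_shift(), seed = 11)
  gspec <- generator_spec(n_classes = 3)
  dspecs <- lapply(c("mae", "cce", "dice"), function(l) discriminator_spec(loss_type = l))
  cfg <- train_config(epochs = 5, seed = 13,
                      dropout = dropout_config(sigma = 0.1, n_samples = 5, seed = 13))
  fit <- train(train_set, val_set, gspec, dspecs, cfg)
  .run_cache$spec <- spec
  .run_cache$train_set <- train_set
  .run_cache$val_set <- val_set
  .run_cache$ood_set <- ood_set
  .run_cache$fit <- fit
  as.list(.run_cache)
}
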