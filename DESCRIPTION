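Package: begas
Title: Bayesian Ensemble Adversarial Networks for Long-Tailed Medical Image
    Segmentation and Out-of-Distribution Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a conditional generative adversarial framework with a single
    stacked-hourglass generator and an ensemble of Markovian (patch) discriminators
    for semantic segmentation of long-tailed medical images. Multiplicative
    Gaussian weight noise (dynamic Monte-Carlo dropout) turns the trained
    generator into a configuration ensemble from which predictive moments are
    estimated; the second moment carries a class-frequency offset so rare (tail)
    classes receive higher uncertainty, and the pooled model disagreement yields a
    per-image score for out-of-distribution detection. Includes a seeded phantom
    generator emulating background/organ/lesion pixel imbalance, segmentation and
    calibration metrics (average symmetric surface distance, F1, expected
    calibration error, negative log-likelihood, AUROC), and a command-line
    interface for simulation, training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    png,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    RNifti,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
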