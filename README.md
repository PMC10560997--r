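# begas

Bayesian ensemble adversarial networks for long-tailed medical-image
segmentation and out-of-distribution (OOD) detection.

## The problem

Medical image collections are long-tailed: background pixels outnumber organ
pixels by orders of magnitude and lesion pixels by three or four. Two things
go wrong at once — supervised segmenters collapse onto the majority class,
and deployed models give no warning when inputs come from a different scanner
or population. `begas` implements a single framework that addresses both: a
conditional adversarial segmentation network whose weights are perturbed by
multiplicative Gaussian noise, so one trained generator yields an ensemble of
configurations whose disagreement is a calibrated, rarity-aware uncertainty
signal.

It is aimed at methods researchers who want the mechanism reproducible on a
laptop: everything runs on synthetic phantoms from a seeded generator, with
no downloads and no GPU.

## The model

A stacked hourglass generator G maps an image *x* (and a random vector *z*)
to per-pixel class probabilities. K Markovian (patch) discriminators
D₁…D_K score local patches of (image, label map) pairs, each with a weight
λₖ and an assigned auxiliary loss (ℓ_mae, ℓ_cce or ℓ_Dice). Training
alternates discriminator BCE steps with generator steps under

  min_G max_{D_k}  F( V(D₁,G), …, V(D_K,G) ),
  V(D_k, G) = E_{x,y}[log D_k(x,y)] + λₖ E_{z,y}[log(1 − D_k(G(z,x), y))],

where the aggregation F (sum, average or maximum over the active
discriminators) is redrawn every batch and each discriminator's feedback is
dropped with a configured probability.

Uncertainty comes from dynamic Monte-Carlo dropout: configurations
θ̂ᵢ = θ ⊙ δᵢ with δᵢ ~ N(1, σ²) give N stochastic predictions, aggregated by
their first moment (the prediction) and second moment

  u ≈ diag(1/τ) + (1/N) Σᵢ ŷᵢᵀ ŷᵢ − E[y]ᵀE[y],

with τ the training-split class frequencies — rare classes carry a larger
uncertainty floor. The per-image OOD score is the spatial mean of
tr(u − diag(1/τ)), i.e. pure ensemble disagreement.

## Worked example

Train on 200 long-tailed 64×64 phantoms (background : organ : lesion pixels
pooled at roughly 1 : 1/9 : 1/100), evaluate on 50 held-out images, then
score 50 acquisition-shifted copies:

```r
library(begas)

spec      <- phantom_preset("desk")
train_set <- generate_segmentation_dataset(spec, 200, seed = 7)
val_set   <- generate_segmentation_dataset(spec, 50, seed = 1007)
ood_set   <- apply_domain_shift(val_set, default_ood_shift(), seed = 11)

fit <- train(train_set, val_set,
             generator_spec(n_classes = 3),
             lapply(c("mae", "cce", "dice"),
                    function(l) discriminator_spec(loss_type = l)),
             train_config(epochs = 5, seed = 13,
                          dropout = dropout_config(sigma = 0.1, n_samples = 5,
                                                   seed = 13)))

evaluate_model(fit, val_set)
#>    class precision recall    f1  assd n_images    ece    nll
#> 1 lesion     0.758  0.921 0.818 0.477       50 0.0635 0.0725
#> 2  organ     0.987  0.979 0.983 0.160       50 0.0635 0.0725
#> 3  macro     0.873  0.950 0.900 0.319       50 0.0635 0.0725

class_uncertainty(fit, val_set[1:20])
#>        class  mean_u disagreement n_pixels
#> 1 background    1.12      1.4e-04    73118
#> 2      organ    9.90      2.0e-03     8047
#> 3     lesion  121.65      1.5e-03      755

sc <- dplyr::bind_rows(ood_scores(fit, val_set), ood_scores(fit, ood_set))
auroc(sc$score, sc$domain_tag == "ood")
#> [1] 0.8432
```

Reading the output: the head (organ) class is segmented almost perfectly
(F1 0.98, surface distance a sixth of a pixel) and even the 1:100 lesion
class is largely recovered at this seed. The uncertainty ranking is the
framework's stable claim: lesion-pixel uncertainty (`mean_u`, the diagonal
of u at the pixel's true class) sits two orders of magnitude above
background, driven by the 1/τ rarity floor, with the model-disagreement
component also an order of magnitude higher on foreground than background.
Ensemble disagreement separates shifted from in-distribution images at
AUROC 0.84 without ever seeing OOD data in training (this image-level score
is the most seed-sensitive of the three results). Training takes about
2½ minutes on one CPU.

`autoplot(fit$history)`, `plot_ood_scores(sc)` and `plot_uncertainty_map()`
visualise the loss trajectories, score separation and per-pixel uncertainty;
`tidy(fit)` / `glance(fit)` return the trajectory and a one-row summary.

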