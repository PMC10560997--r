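---
title: "Bayesian ensemble adversarial segmentation with Monte-Carlo weight noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian ensemble adversarial segmentation with Monte-Carlo weight noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Real-world medical image collections are long-tailed: a background class owns
almost every pixel, organs a few percent, and the clinically interesting
lesions a fraction of a permille. A segmentation model trained by maximum
likelihood happily predicts the majority class, and a deployed model has no
way to say "this scanner/population looks unlike my training data". `begas`
addresses both with one mechanism: a conditional adversarial segmentation
network whose weights are perturbed by multiplicative Gaussian noise, turning
a single trained generator into an ensemble of configurations whose
disagreement is a usable uncertainty signal.

## Model

**Generator.** A stacked hourglass network maps an image $x$ (plus a random
vector $z$ injected at each bottleneck) to per-pixel class probabilities.
Each hourglass stage downsamples three times (2x max pooling) to an
8x-coarser bottleneck and upsamples back with skip connections; two stages
allow repeated bottom-up/top-down re-estimation. Every convolution except the
1x1 classification head is followed by affine instance normalisation and a
leaky ReLU (negative slope 0.2). Conv weights are initialised from a
zero-mean Gaussian with standard deviation 0.001; the normalisation keeps
activations O(1) at that scale (without it, learning only starts once the
weights have grown for several epochs), and the leak matters at the same
init — with plain ReLU, enough units start dead that a substantial fraction
of seeds never escape the all-background prediction basin within the
training budget, whereas with the leak every seed tested does. The raw image
is additionally concatenated onto the head's input (an input skip): a fully
instance-normalised feature path is blind to global intensity statistics, so
without the skip the weight-noise ensemble cannot see the acquisition shifts
its disagreement is meant to detect.

**Discriminators.** $K$ Markovian (patch) discriminators score local
patches of an (image, label-map) pair as real or fake; the default receptive
field is 16 px, matched to desk-scale 64x64 phantoms. Each discriminator $k$
carries a weight $\lambda_k$ and an assigned auxiliary segmentation loss
(mean absolute error, categorical cross-entropy, or Dice). Discriminators
are randomly initialised (He); no pretraining is used.

**Objective.** Discriminators maximise the conditional value function

$$V(D_k, G) = \mathbb{E}_{x,y}[\log D_k(x,y)] +
  \lambda_k\, \mathbb{E}_{z,y}[\log(1 - D_k(G(z,x), y))],$$

trained in practice with binary cross-entropy on real/generated patch grids.
The generator receives the feedback of the ensemble aggregated by a function
$F$ — the sum, average or maximum of the active per-discriminator values —
plus the active discriminators' auxiliary losses. $F$ is redrawn from
`mode_probs` at the end of every batch, and each discriminator's feedback is
dropped with probability `drop_prob` (all discriminators keep training;
dropping only silences their feedback to the generator). Every per-batch mode
and activity decision is logged in the training history so the stochastic
control is auditable.

**Dynamic Monte-Carlo dropout.** With $\theta = \{\theta_1,\dots,\theta_d\}$
the generator parameters, a configuration is $\hat\theta_i = \theta \odot
\delta_i$, $\delta_i \sim \mathcal N(1, \sigma^2)$ elementwise. $N$
configurations form an ensemble; predictions are aggregated by the first
moment $E[y] \approx \frac1N\sum_i \hat y(x,\hat\theta_i)$ and uncertainty by
the second,

$$u \approx \mathrm{diag}(1/\tau) + \tfrac1N\sum_i \hat y_i^{\mathsf T}\hat y_i
  - E[y]^{\mathsf T}E[y],$$

with $\tau$ the normalized class frequencies of the training split. The noise
is active during training (gradients are chained through $\delta$) and at
prediction time. "Dynamic" is implemented as a pluggable $\sigma$ schedule
(constant by default, linear decay available); nothing in the framework
depends on which schedule is chosen.

## Interpreting $\tau^{-1} I_C$

$\tau$ is defined as a frequency *vector*, yet the offset is written like a
scalar precision. The package reads it as $\mathrm{diag}(1/\tau_c)$ (default
`tau_mode = "vector"`), so rare classes receive a larger constant uncertainty
floor — this is exactly the "rare classes are more uncertain" mechanism, and
it is why `class_uncertainty()` reports both the full diagonal (`mean_u`) and
the model-disagreement component with the offset removed (`disagreement`).
The scalar-precision reading (`tau_mode = "scalar"`) is available as a
configuration switch. The per-image OOD score excludes the constant offset
entirely: it is the spatial mean of
$\mathrm{tr}(u - \mathrm{diag}(1/\tau))$, i.e. pure member disagreement, so
confidently handled in-distribution images score near zero regardless of
class rarity.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `sigma` | 0.1 | noise sd, >= 0 | weight-noise level; 0 disables the ensemble. 0.1 is a typical multiplicative-Gaussian dropout level; the framework's behaviour is monotone in it (more noise, more disagreement) |
| `n_samples` (N) | 5 | count | MC configurations at prediction time; variance of the moment estimates shrinks as 1/N |
| `K` | 3 | count | discriminators; K = 1 reduces exactly to a conditional GAN |
| `lambda_k` | 1 | >= 0 | per-discriminator weight of the fake term |
| `mode_probs` | uniform | simplex | distribution over sum/average/maximum feedback aggregation |
| `drop_prob` | 0.1 | [0, 1) | per-batch probability a discriminator's feedback is silenced |
| `aux_weights` | 10 each | >= 0 | supervised-vs-adversarial balance (below) |
| `learning_rate` | 2e-4 | — | Adam, beta1 0.9, beta2 0.999, weight decay 1e-4, batch size 1 |
| `patch_receptive_field` | 16 | px | patch size a discriminator score sees |

**Why `aux_weights = 10`.** With auxiliary losses and adversarial feedback
equally weighted, the patch discriminators learn within a few dozen batches
that real label maps are crisp and overwhelmingly background, and the
generator's cheapest way to fool them is to predict background everywhere:
the head-class F1 collapses to 0 at desk scale. Up-weighting the supervised
losses (here 10 per loss; conditional image-to-image translation commonly
uses a factor of 100 for the reconstruction term) keeps the segmentation
signal dominant while the adversarial term still shapes boundary statistics.
The weights are exposed in `objective_config()`.

## What the phantom generator emulates — and what it does not

`generate_segmentation_dataset()` renders a background field, one ellipse per
organ class, and 0–3 small elliptical blobs per image for each tail class,
with Gaussian per-class intensities plus a shared low-frequency field,
clipped to [0,1]. Presets mirror the pixel-imbalance regimes of liver-tumour
style data (background:organ:lesion at 1 : 1/400 : 1/1400), multi-organ data
(four organs at 1/40–1/400), and a desk-scale `"desk"` preset
(1 : 1/9 : 1/100) whose head class is learnable from a few hundred 64x64
images while the lesion class stays rare.

Ratios are enforced pooled over the dataset, not per image — a 1:1400 class
cannot appear in every 64x64 image. Tail-blob counts per image follow a
low-discrepancy allocation (the rate's running integer part), so the pooled
fraction is on target without inflating between-dataset variance; blob sizes,
shapes and positions are random. The expected pixel yield of a blob is
calibrated by rasterising a grid of diameters, not from the continuous area
formula, so discretisation bias does not shift the pooled ratio. Organ
budgets are inflated by the expected pixels carved out by lesions placed
inside them.

Per-image randomness comes from counter-indexed streams derived from the
master seed (`substream_seed()`), so datasets are bit-reproducible, call-order
invariant, and extending `n_images` never reshuffles earlier images.

The phantoms are deliberately not anatomical: no 3D structure, no organ
texture beyond Gaussian noise plus a smooth field, boundaries that are
ellipse arcs rather than anatomy. Passing tests on phantoms therefore shows
that the mechanisms work (imbalance handling, uncertainty ranking, OOD
separation under acquisition shift), not that the defaults transfer to CT or
MR data.

The domain-shift model (`shift_spec`) composes an additive intensity offset,
a contrast change about mid-gray, stationary Gaussian texture noise and an
optional resolution round trip; the default OOD shift is offset 0.15,
contrast 1.25, noise sd 0.05 — a moderate "different scanner" shift chosen
a priori. The identity shift returns its input unchanged (such data is
in-distribution by definition); non-identity shifts never touch masks or
labels.

## Numerical choices

* Dice uses $\epsilon = 10^{-6}$ and averages over foreground classes only.
* Cross-entropy clamps probabilities at $10^{-12}$ (clamped pixels counted);
  its gradient uses a $10^{-7}$ floor for stability.
* Discriminator scores are clamped to $(10^{-12}, 1-10^{-12})$ before logs.
* The generator uses the non-saturating adversarial form
  $-\log D(\mathrm{fake})$ by default; the literal saturating form is
  selectable (`adversarial = "saturating"`).
* ASSD boundaries use 4-connectivity with image borders counting as outside;
  empty masks yield an `Inf` sentinel with a flag rather than an error.
* ECE uses 10 equal-width bins on (0,1]; AUROC is the midrank Mann–Whitney
  statistic (ties count 1/2).
* Multi-class metrics are macro-averaged over foreground classes; classes
  absent from both prediction and truth are flagged undefined and excluded.
* Instance-norm uses variance floor $10^{-5}$; Adam uses $\epsilon=10^{-8}$
  and L2-style weight decay added to gradients.
* Divergence (non-finite loss or gradient) aborts with the last finite
  parameter set attached to the condition.

## Design decisions that were genuinely open

* **Where the noise acts:** on weights ($\theta\odot\delta$), not
  activations; the multiplicative form is the one the moment formulas assume.
* **$z$ during MC prediction:** held fixed across members by default so the
  spread isolates weight-noise (epistemic) uncertainty; `resample_z = TRUE`
  folds in the generator's conditional variability.
* **Dropped discriminators keep training:** dropping only silences feedback
  to the generator; the discriminator's own BCE updates continue. The
  aggregation is taken over the non-dropped subset.
* **Cross-validation:** "threefold" and "80/20" are jointly impossible as a
  partition, so `cross_validate()` runs three repeated seeded 80/20 splits
  and reports mean ± sd; each report records the splits.
* **Update ratio:** one discriminator step (each k) and one generator step
  per batch.
* **Learning rate:** constant by default; "started from" suggests a schedule,
  so a linear decay is exposed but off.
* **Classification tasks** reuse the segmentation machinery by broadcasting
  the image-level label to a constant label map; the predictive mean's
  spatial average gives the class probability. Nothing classification-
  specific is claimed beyond that reduction.
* A second, global discriminator pathway (global feature vectors alongside
  local patches) is mentioned in passing in the source material but never
  formalised; it is not implemented.

## Problem sizes

The bundled experiments run at 64x64 with 200 training images, 50 validation
images, 50 shifted OOD images, 5 epochs, K = 3 and N = 5 — the smallest
configuration at which the head class is reliably learned, the tail class
ranks above background in uncertainty, and shifted images separate from
in-distribution ones. Training takes a couple of minutes on one CPU.

## Known limitations

* The lesion class at 1:100 is often poorly segmented at this scale; the
  framework's reliable claim at desk scale is the uncertainty ranking, not
  tail-class recovery.
* Out-of-distribution separation at desk scale varies with the training
  seed: some runs detect the default acquisition shift much more strongly
  than others. The uncertainty *ranking* across classes is stable; the
  image-level disagreement score is the more fragile quantity.
* No aleatoric/epistemic decomposition beyond the single second moment `u`.
* No 3D convolutions, no pretrained discriminators, no GAN stabilisers
  (spectral norm, gradient penalties) — faithful to the base method.
* Instance norm makes single-image statistics part of the model; predictions
  on constant images are degenerate.
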