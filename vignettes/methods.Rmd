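---
title: "Hybrid convolution–attention pneumonia classification with adaptive dropout: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid convolution–attention pneumonia classification with adaptive dropout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`pneumonet` implements a compact hybrid image classifier for four-class
pneumonia screening on grayscale chest images (Normal, Bacterial, Viral,
Fungal pneumonia), together with a population metaheuristic that adapts the
dropout rate while the network trains.  The forward pass is a single
sequential chain:

1. **Fire modules** (SqueezeNet style): a 1×1 "squeeze" convolution, ReLU,
   then parallel 1×1 and 3×3 "expand" convolutions whose outputs are
   channel-concatenated.  Output channels are always `expand1 + expand3`.
2. **Max pooling** over non-overlapping windows (no implicit padding; the
   spatial size must divide evenly).
3. **Patch tokenization**: the pooled map is cut into non-overlapping
   P×P patches (row-major over the patch grid), each flattened and linearly
   embedded; a learned per-position encoding is added.
4. **Self-attention blocks**: per head, `softmax(Q Kᵀ / √d_h) V` with learned
   projections, heads concatenated, output-projected, plus a residual
   connection.  With one head this is exactly the single-head scaled
   dot-product formulation; the multi-head form is the standard extension.
5. **Token grid back to a spatial map**, then a **depthwise-separable
   residual block** (per-channel 3×3 depthwise convolution, 1×1 pointwise
   channel mix, each ReLU-activated, plus the block input — through a 1×1
   projection when channel counts differ).
6. **Global average pooling**, an affine head, softmax, argmax (ties go to
   the lowest class index).

All convolutions are zero-padded, stride-1 cross-correlations.  Forward and
backward passes are written in this package (base R orchestration over
BLAS matrix products, with compiled im2col+GEMM kernels for the 1×1/3×3
convolutions and max pooling); there is no deep-learning framework
dependency, and the backward pass is verified against central finite
differences in the test suite's spirit (worst relative error ~1e-4 at
double precision in development checks).

### Default ("tiny") configuration

`net_config()` defaults target CPU-scale experiments on 64×64 inputs: two
fire modules (squeeze 8, expand 16+16), 2×2 pooling, 4×4 patches, embedding
dimension 64 with 4 heads and 2 attention blocks, a 64-channel separable
block, and a 4-class head.  About 105k parameters.

### Numerical choices

* **Initialization** is a seeded uniform fan-in scheme with explicit gains:
  `U(±√6/√fan_in)` before ReLU (He), `U(±√3/√fan_in)` for the linear
  stages (Glorot-style), and a small `U(±0.3/√fan_in)` output layer so the
  initial softmax is near-uniform.  The gains matter: an unscaled
  `1/√fan_in` limit attenuates activation variance roughly six-fold per
  ReLU layer, and in our measurements the resulting network never left
  chance level.
* **Dropout** is inverted dropout with one shared rate.  Sites are
  configurable (`dropout_sites`): after tokenization, after each attention
  block, and/or after global average pooling.  The default is the
  classifier-head (GAP) site only: with all three sites active at rate 0.5,
  the default-sized network stays at chance accuracy for tens of epochs on
  the synthetic task, while head-only dropout trains reliably.  Evaluation
  mode always disables dropout, so predictions are dropout-invariant.
* **Ties** in the argmax go to the lowest class index; softmax is computed
  with the usual max-subtraction; cross-entropy clamps probabilities at
  1e-12.

## Preprocessing

The conditioning chain is: global histogram equalization (optional,
default on) → bilinear resize to the configured input size → (train-time
augmentation, optional) → z-score normalization.  Normalization statistics
(pooled mean and population sd over all pixels, sd floored at 1e-8) are
computed from training images only, so validation or test pixels can never
leak into them — the test suite asserts that perturbing validation images
changes neither the statistics nor the first weight update.

Equalization uses the textbook 8-bit formula
`round((cdf(v) − cdf_min)/(N − cdf_min)·255)`; a constant image is returned
unchanged because the formula's denominator degenerates.  Whether inputs
should be equalized at all is ambiguous in the protocol this package
follows, and measurement settles it for the synthetic task: global
equalization is a per-image rank transform, so a diffuse mean-opacity shift
(the Viral-vs-Normal signature) is mapped to the lung band's pixel-mass
share and vanishes — the d′ of the mean-lung-intensity feature drops from
15.2 to −0.2, and a trained network then confuses exactly those two
classes.  It is therefore exposed as `train_control(equalize=)` with
default **off**; enable it when per-image contrast normalization matters
more than absolute intensity levels (e.g. heterogeneous acquisition
settings).

Augmentation applies, in order, a uniform rotation, a horizontal flip, and
a uniform scaling about the center.  Defaults are mild (±5°, flip 0.5,
scale 0.95–1.05): at 64×64 with fine rib-band structure, ±15°
rotations leave an image correlated with its original by as little as
r ≈ 0.15, and training then fails to move off chance within the 30-epoch
budget used here.  More importantly, the study protocol this package
mirrors states in its own discussion that augmentation was *not* applied,
so `train_control(augment=)` defaults to `NULL`; pass `augment_spec()` to
enable it.

## Training

`pneumonet()` trains with Adam (β₁ = 0.9, β₂ = 0.999) on categorical
cross-entropy, batch size 32, with plateau learning-rate decay (×0.5 after
5 stagnant epochs) and early stopping (10 stagnant epochs), both driven by
validation loss.  The protocol default learning rate is 1e-4 with adaptive
decay; for the desk-scale experiments shipped with the package (hundreds of
64×64 images, ≤30 epochs) the rate was chosen by a small grid search — the
same procedure the protocol itself used — and 1e-3 is employed there, since
1e-4 does not move off chance within that budget at this data scale.

`pneumonet_cv()` runs stratified k-fold cross-validation (per class, seeded
shuffle then round-robin, so per-class fold counts differ by at most one).
Each fold trains a fresh seeded model on the other k−1 folds and is scored
on the held-out fold, which also serves as the early-stopping validation
split — a pragmatic desk-scale choice that makes per-fold metrics mildly
optimistic; an optional stratified test holdout, carved out before folding
and never seen by any fold, gives the unbiased figure.

## The adaptive dropout search

The dropout rate is the single most influential regularization
hyperparameter here, and the package tunes it online with a population
metaheuristic over the interval [0.1, 0.6]:

* **Exploration (water-strider style, odd iterations)**: each non-best
  candidate d moves by `α·u·(best − d) + α·g·span` (u uniform, g standard
  normal); if the move lowers fitness it is treated as a failed "ripple"
  and the candidate is instead repelled, `d − α·u'·(best − d)`.  The
  tension coefficient α starts at 0.7 and decays ×0.95 per iteration.
* **Refinement (genetic style, even iterations)**: restricted to the top
  half of the population; tournament-selected parents produce arithmetic-
  crossover children (probability 0.8), Gaussian mutation with sd
  0.075·span (probability 0.15), and children replace the current worst
  candidate only when fitter (elitist replacement).

Customary ranges are populations of 10–30, 20–50 iterations per round,
crossover probability ~0.8, mutation 0.1–0.2, and local mutation scale
0.05–0.1; `dropout_search_control()` defaults sit mid-range (20, 30).

**Noise handling.**  Validation-based fitness is stochastic, and a
population search that trusts single evaluations is captured by lucky
draws: with N(0, 0.01) fitness noise, the raw "best evaluation ever seen"
lands more than 0.03 from a known optimum in roughly a quarter of runs.
The search therefore (i) caches fitness per rate (rounded to 1e-4) as a
running mean over repeated draws, (ii) re-scores the incumbent once per
iteration and races the leader to at least five draws at the end of a
round, and (iii) — when repeated draws reveal that the fitness is actually
stochastic — returns the consensus (mean) of the top half of the final
population ranked by averaged fitness, for the same reason CMA-ES returns
its recombination mean rather than the best sampled point.  For a
deterministic fitness the returned value reduces exactly to the argmax.
With this estimator the search recovers a known optimum to within 0.03 in
19 of 20 seeded runs (median error 0.0099), roughly 2.7× tighter than
uniform random search with the same evaluation budget.

**Training integration.**  When `train_control(dropout_search = TRUE)`,
one search round runs every `search_interval` epochs (default 5), warm
started from the previous round's population.  A candidate rate is scored
by cloning the current weights and optimizer state, training `eval_budget`
fixed mini-batches at that rate, and evaluating macro F1 (default) on a
capped validation subset; the same batches and subset are used for every
candidate in a round, and each candidate's evaluation is seeded by its own
rate, making fitness deterministic per candidate (so elite re-scoring is
skipped there).  Desk-scale rounds use a small search (population 10, 20
iterations by default; the experiments shipped in the tests use 6
iterations per round) because each evaluation costs a training step — the
20–50-iteration range quoted above reflects the original GPU-scale
setting.

## The synthetic data generator

The generator emulates the *statistical* structure of four-class chest
image collections, not radiology: two fixed elliptical lung fields on a
body background (X-ray: full-field body with low-frequency rib-band
sinusoids; CT: circular cross-section, 1.5× lesion contrast), plus
class-specific opacity signatures —

* Bacterial: one focal high-opacity blob, radius 8–15% of the image width;
* Viral: diffuse bilateral low-contrast texture (sum of random sinusoids);
* Fungal: 3–6 small nodules, radius 2–4%;
* Normal: clear fields.

Ground-truth lesion masks accompany every image (empty exactly for
Normal).  Lesion contrast scales with `severity`; Gaussian noise of sd
`noise_sd` is added and intensities clipped to [0, 1].  Geometry and noise
draw from separate counter-derived substreams per image, so generation is
insertion-order independent and, at severity 0, every class is
pixel-identical to Normal.  The lesion contrasts (0.5, 0.05, 0.55 of the
intensity range, before the CT multiplier) were chosen once so that the
class-conditional mean lung intensity orders Bacterial > Viral > Normal at
severity ≥ 0.5 and a depth-2 decision tree on two handcrafted features
(mean lung intensity, bright-blob count) exceeds 70% accuracy — separable,
but not trivially so at the default noise level.

What passing tests on these images do **not** show: robustness to real
anatomical variability, scanner differences, label noise, or class
imbalance.  The generator defaults (50 per class, 64×64, severity 1,
noise 0.05) are desk-scale placeholders — the original study never
characterizes its datasets (counts, balance, resolution).

## Saliency

`grad_cam()` differentiates the pre-softmax class score with respect to
the activations of the last spatial layer (the pointwise convolution of
the separable block, post-activation, just before GAP).  Because the head
is GAP + linear, that gradient is spatially uniform and equals
`w_fc[class, c]/n_spatial` per channel; the map is the rectified weighted
sum of activations, bilinearly upsampled to the input size and min–max
normalized.  Differentiating the logit (not the probability) makes the map
invariant to adding a constant to all logits.  An all-zero pre-
normalization map is returned as zeros with a `flat` attribute rather than
being rescaled.

## Evaluation panel

`classification_report()` computes one-vs-rest precision, recall
(sensitivity), specificity and F1 per class, macro (unweighted) averages,
accuracy and error rate; zero-denominator metrics are reported as 0 and
flagged, which keeps macro averages total.  `auc_roc_ovr()` uses the
Mann–Whitney rank formulation (ties counted ½); classes without positives
or negatives are excluded from the macro mean with a warning.
`anova_one_way()`/`anova_from_ss()` produce the textbook one-way table
(MS = SS/df, F = MS_b/MS_w, upper-tail p); zero within-group variance
yields F = ∞ with a flag.  `class_correlation()` correlates class-mean
feature vectors (typically the GAP features), the quantity behind
class-correlation heatmaps.

## Experiment sizes used in the shipped tests

All shipped experiments run on one CPU: the end-to-end task uses 4×200
synthetic X-ray-like images at 64×64 (15% test holdout, 15% validation
split), up to 30 epochs with early stopping; the adaptive-vs-fixed dropout
comparison trains the adaptive arm for 20 epochs with search rounds every
5 epochs (population 10, 6 iterations, 1 mini-batch per candidate
evaluation, 64 validation images per score) against the epoch-matched
fixed run (per-epoch seeding makes the fixed run's first k epochs
identical to a k-epoch run); determinism checks use a reduced 32×32
configuration.  These sizes are the package's own choices
for reproducible desk-scale runs and are deliberately far below the
original study's scale, whose headline accuracies depend on external
datasets that are not identified by accession.

## Known limitations

* No layer/batch normalization (the sequential chain is implemented as
  specified), so training is sensitive to initialization scale and
  learning rate; the defaults reflect that.
* Single shared dropout rate (by design — the optimizer tunes a scalar).
* The synthetic generator's simplicity means near-ceiling performance is
  expected at severity 1; it is a test harness, not a benchmark.
* CPU-only; minutes per training run at the default scale.
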