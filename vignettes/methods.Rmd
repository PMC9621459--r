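---
title: "Uncertainty-gated skin-lesion diagnosis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-gated skin-lesion diagnosis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Automated dermoscopy diagnosis faces two obstacles to clinical use: a
convolutional classifier returns a point prediction with no notion of its own
confidence, and it offers no account of *which pixels* drove the decision.
`skinet` implements a two-stage pipeline that addresses both. A Bayesian
MultiResUNet first segments the lesion; if the segmentation is confident, the
classifier receives a lesion-focused crop with hair, droplets and background
removed, otherwise the original image. A Bayesian dropout classifier then
predicts one of several diagnostic categories; if its predictive entropy is
too high, the case is *referred* to a clinician instead of being diagnosed.
Every diagnosis is accompanied by a saliency map.

## Uncertainty model

Both networks carry Bernoulli dropout layers (rate 0.5 by default, the
operating point at which Monte-Carlo uncertainty estimates are informative
without crippling the fit). Three posteriors over the output are available:

* **Epistemic** (model uncertainty): B stochastic forward passes with dropout
  active on the unmodified input; the mean over passes approximates the
  posterior predictive under a Bernoulli weight distribution.
* **Aleatoric** (data uncertainty): V test-time-augmented copies (random
  horizontal/vertical flips, rotations uniform in [-65, 65] degrees — the same
  family used for training augmentation) passed with dropout *off*. For
  segmentation, each output map is carried back through the inverse geometric
  transform before averaging so the posterior lives in the input frame.
* **Combined**: M passes with a fresh augmentation *and* a fresh dropout mask
  each; this is the default gating mode.

The scalar uncertainty is the predictive entropy of the averaged probability
vector, `phi = -sum(p * log p)` in nats, normalized linearly into [0, 1].
Normalization bounds default to the analytic range — 0 to `log(N)` for an
N-class classifier, 0 to `log(2)` per pixel for segmentation — with an
empirical calibration-batch mode (`empirical_entropy_bounds()`) available,
since finite Monte-Carlo sampling rarely attains the analytic extremes. A
prediction is *certain* iff `phi_norm < phi_T`; equality counts as uncertain
because only the strict inequalities are specified by the gating rule, and
deferring a borderline case is the conservative choice for a referral system.
Argmax ties break toward the lowest class index.

Thresholds default to `phi_T = 0.25` for segmentation and `0.35` for
classification, the empirically tuned operating points of the published
system. The segmentation gate needs a scalar, yet entropy is per pixel; the
default reduction is the mean per-pixel binary entropy divided by `log(2)`
(so it lies in [0, 1]), with the fraction of pixels above half the binary
maximum available as an alternative (`seg_reduction = "fraction_uncertain"`).
The mean-entropy reduction weights all pixels equally, so large certain
backgrounds dilute boundary uncertainty; this is the main reason a desk-scale
segmenter under 0.5 dropout tends to sit above the 0.25 gate and route the
original image — the same routing the full-scale system applies to its
uncertain segmentations.

Certainty crossed with correctness yields four categories (correct-certain,
correct-uncertain, incorrect-certain, incorrect-uncertain); the diagnostic
accuracy `A(phi_T) = (L_cc + L_iu) / total` scores how often the gate does
the desirable thing — trusting correct predictions and flagging wrong ones.

## Networks

No tensor/autodiff library is available to R in this toolchain, so the
package carries a small reverse-mode tape engine (`R/autodiff.R`,
`R/ops.R`): convolutions are `im2col` plus one BLAS matrix multiplication,
and every operation registers an analytic backward closure. All gradients
are verified against central finite differences in the test suite.

The **segmenter** is a MultiResUNet: four encoder stages of MultiRes blocks
(three chained 3x3 convolutions approximating 3x3/5x5/7x7 receptive fields,
concatenated, plus a 1x1-convolved residual), 2x2 max pooling with a dropout
layer after each pooling, a fifth MultiRes bridge, and a mirrored decoder of
2x2 transposed convolutions (each followed by dropout) with Res-path skip
connections of 4/3/2/1 residual conv blocks. A final 1x1 convolution with
sigmoid emits the probability map. The MultiRes width is `W = alpha * U`
with `alpha = 1.67`, split `floor(W/6)`, `floor(W/3)`, `floor(W/2)` across
the three convolutions — the canonical MultiRes parameterization, which the
architecture figures imply but do not enumerate. All convolutions use batch
normalization and ReLU except the sigmoid output.

The **classifier** is a compact Bayesian CNN: four conv/batch-norm/ReLU/pool
stages of width `base_filters * (1, 2, 4, 8)`, global average pooling, and a
dense softmax head. Dropout insertion points are configurable
(`dropout_positions`); the default — after the last two conv stages and
before the dense head — perturbs high-level features enough to produce
Monte-Carlo variance while leaving early feature extraction intact. This
mirrors how full-size backbones are made Bayesian by dropout placement
search, at a width that trains on one CPU; the stochastic-forward contract
(`set_stochastic_mode()`, `net_predict()`) is identical at every width, and
the contract tests run at `base_filters` 4 and 8.

Batch normalization always uses frozen running statistics outside training,
so Monte-Carlo sampling perturbs *only* the dropout masks; mixing batch
statistics across MC passes would confound the epistemic estimate with
batch-composition noise.

## Training

Adam at learning rate 1e-3, batch size 16, binary cross-entropy for the
segmenter (pixel-wise, computed from logits in softplus form for numerical
stability) and categorical cross-entropy — the standard multi-class
extension of the binary loss — with one-hot targets for the classifier. No
learning-rate schedule, weight decay or early stopping is applied by
default. Weight initialization (He normal), data shuffling and dropout masks
all draw from one seeded RNG stream, so a `train_config(seed = )` makes the
entire run bit-reproducible. Validation splits are seeded 80/20 shuffles
(`split_dataset()`).

## Synthetic dermoscopy data

The generator (`generate_sample()`, `generate_dataset()`) exists so the
whole pipeline can be exercised end-to-end with pixel-exact ground truth: a
warm skin-tone background with a mild gradient, one elliptical lesion whose
base color and sinusoidal texture come from a per-class palette, additive
Gaussian pixel noise, and — each with probability `artifact_rate` — dark
curved hair strokes and bright circular droplets painted *over* the image
but never into the mask. Artifacts are first-class because occlusions are
precisely what drives real dermoscopy uncertainty; they let referral gating
be provoked on demand. The ellipse axes are `r*s` and `r/s`, so area is
independent of eccentricity and pixel counts can be checked against
`pi * r^2` analytically.

Default conditions, chosen once: seven classes whose palette colors are
pairwise separated by more than three times the default noise standard
deviation (0.05) — guaranteeing learnability — with two pairs (4/5 and 6/7)
deliberately close in color to emulate visually confusable diagnostic
categories; `artifact_rate` 0.3; lesion radius 0.15-0.30 of the image side.
The default image size is 224x224 (the published segmentation input size);
the test suites generate at 32x32, where the full study (200 samples per
class, both networks trained, posteriors sampled) runs on one CPU in
minutes. What the generator does **not** model: real lesion morphology
(asymmetry, border irregularity, color variegation within the palette),
camera vignetting, or the severe class imbalance of clinical archives. Tests
passing on this data therefore demonstrate that the machinery — gating,
posteriors, saliency, metrics — behaves as specified, not that the desk
networks would diagnose real dermoscopy images.

Rotation fill uses the per-sample background tone (stored by the generator,
or estimated as the border median for arbitrary images) — leaving black
corners would inject artificial out-of-distribution signal into the
aleatoric posterior, which we observed as inflated referral rates before
adopting the background fill. Masks are resampled nearest-neighbour under
all geometric transforms so they stay binary.

## Saliency

Guided Backpropagation (ReLU backward signals zeroed where either the
incoming gradient or the forward input was negative), Grad-CAM (globally
average-pooled gradients of the pre-softmax class score weighting the last
conv stage's activations, rectified and bilinearly upsampled), Guided
Grad-CAM (their elementwise product), integrated gradients (midpoint
Riemann path integral, 64 steps by default; channel sums are signed so the
completeness axiom is testable), and XRAI: integrated gradients averaged
over black and white baselines, a Felzenszwalb graph over-segmentation at
three scales (k = 0.1, 0.3, 0.9 on the [0, 1] color-distance scale — chosen
to give a coarse/medium/fine region mix on [0, 1] RGB images), and greedy
region ranking by attribution gain per newly covered pixel. No R package in
the toolchain provides Felzenszwalb segmentation or bicubic resampling, so
both are implemented here (union-find with the `k/|C|` merge criterion;
separable Catmull-Rom interpolation).

Saliency is computed for the model's *predicted* class, since explanations
accompany predictions. Pixel-gradient maps reduce channels by the sum of
absolute values; integrated gradients by the signed sum (required for
completeness). The bokeh-effect benchmark blurs the image (Gaussian, sigma
defaulting to 5% of the smaller side), restores the top 10% most salient
pixels, reclassifies, and scores agreement with the ground truth; at
`top_fraction = 1` it reproduces plain accuracy exactly, which the tests
assert.

## Pipeline

`run_skinet()` follows the gated flow: resize (bicubic, [0, 1]) to the
segmentation input size; sample the configured posterior; if the
segmentation is certain, hand the classifier a lesion-focused image, else
the original; resize to the classification input size (the published sizes
224x224 and 450x600 are the defaults; desk-scale runs shrink both to
32x32); sample the classification posterior; diagnose or refer. The default
handoff is a bounding-box crop with a 10% margin rather than hard
background masking — the published figures show background *removal*, and a
crop preserves local context while excising distant artifacts; pure masking
remains available (`handoff = "masked"`). Empty masks degrade gracefully to
the original image. `evaluate_pipeline()` always records the classifier's
underlying argmax (referred cases land in the uncertain categories), so
category tables and both prediction-accuracy accountings (refer cases
counted, or excluded) can be reported; which accounting the published
88.46% figure uses is not stated, so both are emitted.

## Problem sizes and numerical choices

The shipped suites use: 7 classes x 200 samples at 32x32; classifier
`base_filters = 8` trained 14 epochs; segmenter `base_filters = 4` trained
6 epochs on 200 samples; B = V = M = 20 posterior passes (configurable; 20
is enough for the entropy ranking to stabilize, and the Monte-Carlo
convergence test verifies the 1/sqrt(B) standard-error law). Probabilities
are clipped at 1e-12 before logs in the reference BCE metric; batch-norm
uses eps 1e-5 and momentum 0.9; `0 * log 0 := 0` in all entropies.

One printed-formula discrepancy is handled explicitly: the Jaccard index is
sometimes typeset as `1 - |intersection|/|union|` (a distance) in the
segmentation literature even where similarity-scale values comparable to
Dice are reported; `jaccard()` returns the similarity by default and
exposes `as_distance = TRUE`.

## Known limitations

* Desk-scale networks demonstrate contracts, not clinical performance;
  headline accuracies from full-size backbones on real dermoscopy archives
  are out of scope.
* The pure-R engine is single-threaded apart from BLAS; a 224x224 segmenter
  forward pass takes on the order of a second, so large-scale sweeps belong
  on a compiled stack.
* The segmentation-gate scalar depends on the chosen map reduction; with
  mean entropy and 0.5 dropout, desk-scale segmenters usually exceed the
  0.25 gate (discussed above).
* TTA inversion for segmentation maps is exact for flips but interpolated
  for rotations; boundary pixels acquire a small inversion blur.
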