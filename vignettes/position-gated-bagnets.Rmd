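---
title: "Position-gated bag-of-local-features networks for 3D volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-gated bag-of-local-features networks for 3D volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model, the choices behind
the implementation, and what the synthetic experiments do and do not
show.

## Model

A volume **X** on a common template grid is treated as a bag of
overlapping 3D patches. Two branches produce, for every patch-grid
position (i, j, k):

* a raw **patch response** `x̃_ijk` — encoder `E^s_φ` (receptive field
  `s³`) plus a point-wise linear classifier `C_ψ`, weights shared across
  positions;
* a **gate probability** `g_ijk ∈ [0, 1]` — a point-wise position
  embedding `P_π` (3 → 128 → 256 channels, ReLU after each layer) and
  gate network `G_ρ` (256 → 128 → 16, ReLU after the first layer only),
  whose 16 output maps are averaged per position and passed through a
  sigmoid. Its input is the **position indicator I′**: the normalized
  template coordinates of each patch center.

The image-level response is the normalized gated sum
`z = Σ g·x̃ / Σ g`, and `ŷ = sigmoid(z)`. The product `e = g·x̃` is the
patch-level class evidence: positive values support the positive class,
negative values the negative class, and summing `e/Σg` reproduces `z`
exactly — aggregation is transparent by construction.

Because the gate reads coordinates only, it is identical for all
subjects: it represents where discriminative change appears
*consistently across subjects* in template space, as opposed to
image-conditioned saliency. The `feature_gate` mode (gate fed the encoder
features instead of coordinates) and the `gap` mode (plain global average
pooling) are first-class ablations; `fixed_gate` accepts a precomputed
probability map in place of the learned branch, which reproduces
average-pooling behavior exactly when the map is constant.

### Encoder family and receptive-field arithmetic

The encoder is a stem convolution (kernel 5, stride 2, 32 maps, instance
normalization, ReLU), max pooling (kernel 3, stride 2), and four residual
blocks at 32/64/128/256 maps with stride 1 and valid padding throughout.
After stem and pool the receptive field is 9 voxels per axis with a
patch-center spacing (jump) of 4 — the family minimum. Each 3×3×3
convolution inside a residual block adds `2 · jump = 8` voxels, so
allocating 0, 1, 2, 4, 6 of them yields the family
{9, 17, 25, 41, 57}. The allocation is front-loaded (earlier blocks get
3³ kernels first, at most two per block); the attainable sizes, not the
placement, are the anchored quantity, and placement elsewhere would not
change the family. Residual-block internals are otherwise conventional:
two convolutions with instance norm + ReLU, an identity shortcut that is
center-cropped to the valid-padding extent and point-wise projected when
the channel count changes. The classifier is one point-wise linear layer
with bias; the gating branch uses no normalization layers, and the
position embedding has a ReLU after each of its two layers (whether an
activation sits between embedding and gate network is not fixed by the
architecture's description; the ReLU-after-each choice makes the
embedding a standard two-layer MLP).

Geometry is tracked exactly by the receptive-field recurrence
(`compose_geometry()`): starting from (rf, jump, offset) = (1, 1, 0),
a layer with kernel k, stride s, padding p maps
`rf += (k−1)·jump; offset += ((k−1)/2 − p)·jump; jump *= s`. An
independent gradient-support oracle (`rf_oracle()`) rebuilds any stack as
all-ones single-channel convolutions, backpropagates a one-hot output,
and measures the input support; the two must agree for every shipped
variant, and the tests assert it. Valid padding is used everywhere so
each output position corresponds to a complete patch inside the crop —
this preserves the bag-of-patches semantics at the cost of a slightly
smaller patch grid.

### Coordinates, cropping, and translation behavior

The coordinate space **I** assigns channel c at voxel index i the value
`2i/(n_c − 1) − 1`, normalized over the *full* template grid. Random
cropping (the only augmentation) slices image and coordinate grid with
the same crop specification, without renormalizing the coordinates: a
patch keeps its template coordinates wherever the crop places it. This is
what makes the gating branch translation-*dependent* while the patch
branch stays translation-*equivariant*. Patch centers sit at
`offset + index · jump` in crop voxel coordinates; the shipped stacks
have integer offsets, and fractional centers (possible only with padded
stacks) are resolved by trilinear interpolation of the coordinate grid.

One subtlety: instance normalization computes per-image, per-channel
statistics over the whole crop, so shifting content into or out of a crop
perturbs *all* responses slightly — weight sharing is exactly
equivariant, the normalization statistics are not. The equivariance test
therefore freezes the normalization statistics on a reference crop
(`freeze_norm_stats()`), which turns each normalization layer into a
fixed per-channel affine map; under frozen statistics, shifting the input
by one jump shifts the interior patch responses by exactly one grid
cell. Frozen statistics are an evaluation-only probe, not a training
mode.

### Objective

`L_total = L_cls + λ·L_ent` with λ = 0.01.
`L_cls = −β y^LS log ŷ − (1−β)(1−y^LS) log(1−ŷ)` uses smoothed targets
y^LS ∈ {0.1, 0.9} and weights the terms by the negative-class fraction β
of the *training split only* (never validation or test). The formula
weights the smoothed targets directly — with β = 0.5 and hard targets it
reduces to standard binary cross-entropy halved. `L_ent = −H(G)` is the
negative mean binary entropy of the gate map, pushing the gate toward
0.5 early so region exploration stays open; it applies only when the
gate is learnable (position or feature mode). All probabilities are
clamped at 1e-12 before logarithms; batch reduction is the arithmetic
mean. Because **G** is a function of coordinates alone, the entropy
gradient reaches only π and ρ — the tests verify this structurally
(finite-difference probes of `L_ent` against encoder/classifier
parameters are exactly zero) rather than masking gradients.

## Training procedure

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8 — conventional defaults, recorded
in the run configuration) under a warm-up + cosine schedule: the learning
rate rises linearly from 0 to 1e-4 over 5 epochs, then follows
`0.5·(1 + cos(π·t/T))` down to zero at the epoch budget. Mini-batches of
4; one freshly sampled random crop per training sample per epoch; center
crops for validation and test. Early stopping monitors the validation
balanced label-smoothed cross-entropy *without* the entropy term
(model selection should not reward gate diffuseness), with patience 30;
the best checkpoint by that criterion is returned. Every run is
reproducible bit-exactly from its seed: the seed fixes initialization
(He), shuffling, and crop sampling.

Cross-validation is stratified k-fold (folds from the seed). The
held-out fold is evaluation-only; early stopping uses an inner split
carved from the training folds (default 20%), so no information from the
held-out fold reaches model selection. Transfer learning
(`transfer_init()`, or `train_fold(init_model = )`) copies all four
parameter groups and resets optimizer state — the intended use is
initializing a subtle-contrast task from a model trained on a
strong-contrast task, and the tests verify warm starts reach a better
validation loss than cold starts under an equal small budget.

## Synthetic phantoms

`generate_cohort()` emulates exactly the structure the method assumes:

* a smooth per-subject background (Gaussian-filtered white noise,
  σ = 3 voxels, standardized to unit sd) standing in for anatomy;
* i.i.d. sensor noise (sd 0.1);
* label-irrelevant distractor spheres (6 per subject, radius 4,
  amplitude ±1) placed uniformly at random in *both* classes — these
  are what handicap plain average pooling, mirroring the motivation for
  gating at small patch sizes;
* in positives only, an additive lesion sphere at one fixed template
  position (radius 6, amplitude 0.75 in background-sd units) — the only
  inter-subject-consistent class difference.

The default grid is 48³ with 50 subjects per class: large enough that
the smallest encoder yields a 10³ patch grid (9³ on the 44³ training
crops, the 44/48 ratio mirroring the template-scale 177/193 crop), small
enough that a training run completes in minutes on one CPU. The design
is matched pairs: negative subject j and positive subject j share all
nuisance draws, so the class difference is *exactly* the lesion, a
zero-amplitude lesion makes the classes literally indistinguishable
(trained AUROC ≈ 0.5), and class-mean contrast inside the lesion mask
equals the amplitude. Amplitudes are in units of the background sd, so
0.75 is a clear but local signal against unit-variance anatomy with
stronger (amplitude 1) distractors.

Matched pairs have an evaluation consequence: if the two members of a
pair straddle a train/validation boundary, a model that partly memorizes
backgrounds scores the held-out twin systematically *wrong* (we observed
validation AUROC far below chance under pair-ignorant splits — the
classic grouped-data leakage, inverted). All splitting utilities
therefore accept group identifiers (`stratified_folds(groups = )`,
`cross_validate(groups = )`, and cohorts carry `pair_ids`), and pairs
always stay on one side of a split. Within the training set the pairing
is an asset: a pair can only be separated by using the lesion itself, so
the matched design actively discourages background shortcuts.

What phantoms do **not** emulate: real neuroanatomy, atrophy as
deformation rather than intensity change (the model consumes intensities,
so an additive lesion exercises the same algorithmics), registration
error, multi-site intensity effects, and lesion-size/shape variability.
Passing tests demonstrate that the architecture, gating, losses and
training loop do what they claim under the assumed structure — not
clinical performance.

`localization_score()` quantifies gate quality: each patch-grid position
is mapped to its receptive-field footprint in template space, and the
score is the fraction of total gate mass on patches overlapping the true
lesion mask. The reference point is the uniform gate, whose score is the
overlapping-patch fraction.

## Numerical and design choices

* Whole-image standardization precedes cropping, so train/eval
  statistics do not depend on the sampled crop; the tests pin this order.
* Population quantities use the sample standard deviation; degenerate
  (zero-variance) volumes are rejected.
* float32 is the on-disk precision (NIfTI); computation is double.
* Gate mass below 1e-8 is a degenerate-gate error rather than a division
  by near-zero.
* Accuracy thresholds ŷ at 0.5; AUROC is the rank (Mann–Whitney)
  statistic with averaged ties, cross-checked against an independent
  implementation in the tests.
* Overlay export places each patch value at its patch-center voxel,
  interpolates linearly between centers, zero-fills outside the
  patch-center bounding box, and writes a validity mask alongside so
  downstream thresholding is not confounded by the border; evidence is
  exported pre-normalization (g·x̃) with Σg recorded in the JSON sidecar.
* Checkpoints store a flat named-parameter archive plus a JSON sidecar
  (encoder spec, gating mode, build seed); geometry metadata in overlay
  products suffices to regenerate them bit-exactly.

## Problem sizes used by the test suite

Unit and property tests run on 16³–32³ phantoms with 4–20 subjects and
2–8 epoch budgets — enough to exercise every code path and the
directional properties (amplitude/AUROC monotonicity, entropy
regularization raising gate entropy, transfer speed-up). The end-to-end
recovery test uses the full default cohort (2 × 50 at 48³) with the
smallest encoder and a 36-epoch budget — the package's own scaled
training length, at which the position-gated model comfortably clears
held-out AUROC 0.9 while the identically trained average-pooling
baseline does not match it.

## Known limitations

* Single-channel volumes and binary labels only.
* Isotropic kernels, strides and crops; no dilations, no even kernels.
* The gating branch assumes template alignment; nothing corrects for
  registration failure.
* Instance-norm statistics make responses weakly dependent on crop
  content (see the translation discussion above); this is inherent to
  the architecture, not to this implementation.
* Training is CPU-bound and single-threaded beyond BLAS; the
  implementation favors exactness and reproducibility over throughput.
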