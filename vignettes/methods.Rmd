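---
title: "Models and methods behind hippseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hippseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hippseg` implements a complete hippocampal-subfield segmentation and
lifespan-analysis pipeline at desk scale. This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, and what the
synthetic phantoms do and do not establish about behavior on real MRI.

## The phantom generator

The phantom is a curved tube: a quadratically bent centerline along the
anteroposterior (second) voxel axis, a dentate-gyrus core of relative radius
0.45, and four 90° angular sectors (SUB, CA1, CA2, CA3) in the surrounding
ring. When head/tail caps are requested, the first and last 15% of the
longitudinal coordinate are relabelled to undifferentiated HEAD/TAIL classes,
mimicking rater protocols that do not delineate subfields there. This
geometry was chosen because it reproduces the head–body–tail topology needed
by the anteroposterior composition profile while staying analytically
checkable: the expected body composition is the angular partition itself
(DG fraction `0.45² ≈ 0.20`, each sector `(1 − 0.45²)/4`).

Intensities are `class mean × bias field + noise`: class means default to
distinct but overlapping values (DG 1.0, CA1 0.8, CA2 0.6, CA3 0.45, SUB 0.3,
background 0.1, arbitrary units), the bias field is a low-order polynomial
multiplicative field of relative amplitude 0.2 (enough to make plain intensity
thresholding insufficient and to exercise Z-normalization), and noise is
additive Gaussian with sd 0.05. These are not calibrated to any scanner; they
are chosen so that class separation is possible but requires spatial context.
`phantom_cohort()` jitters curvature (0.25–0.45) and tube radius (±10%) per
subject to emulate anatomical variability.

Head scenes embed a left phantom and its mirror image (right) into a 64³
volume containing an ellipsoidal "head" background with a mild intensity
gradient; the template/atlas pair is the same scene at canonical pose without
noise. Scene labels encode side (right = canonical id + 10), standing in for
a template/atlas pair in segmentation space.

All generators are pure functions of their spec and seed: randomness is drawn
under a locally scoped RNG that restores global state (`with_seed`), so the
same spec is bit-reproducible and label geometry never depends on the noise
seed.

**What passing tests show — and what they do not.** The phantoms exercise the
pipeline's mechanics (registration, cropping, protocol handling, voting,
uncertainty, trajectory recovery) under known ground truth. They do not
establish segmentation accuracy on real MRI: no partial-volume effects,
k-space artifacts, anatomical folding, or inter-rater ambiguity are
simulated.

## ROI localization

Registration is a built-in multi-resolution (3-level pyramid) Nelder–Mead
minimization of the mean squared intensity difference over rigid (translation
+ rotation) or affine (+ per-axis log-scale) parameters, adequate for
synthetic scenes and pluggable for real data (any voxel-to-voxel
`affine_transform` can be substituted). The atlas hippocampus voxels are
mapped through the recovered transform; each side's axis-aligned hull is
expanded by a 16-voxel margin on every side — the margin is a safety
heuristic, so boxes are clamped at image borders rather than erroring — and
crops are Z-normalized (mean 0, sd 1 over the crop) and zero-padded,
centered, to dimensions divisible by 8. Pad amounts and crop boxes are
recorded for exact inverse embedding. Whether right hippocampi should be
mirrored to left chirality before segmentation is protocol-dependent;
`segment(mirror_right = FALSE)` exposes the choice and defaults to off.

## The network

A 3D residual U-Net of configurable depth (default 4 resolution levels;
the desk benchmark uses 3) with:

* **Pre-activation residual blocks** — two 3×3×3 convolutions, each preceded
  by switchable normalization and ReLU, with an identity shortcut; channels
  double per level from `base_channels` (desk default 8).
* **Strided-convolution downsampling** and **transposed-convolution
  upsampling** (kernel 2, stride 2).
* **Attention-gated skip connections**: additive attention with 1×1×1
  projections of the (stride-2) skip and the coarser decoder gating signal,
  ReLU, a 1×1×1 collapse to one channel, sigmoid, and trilinear upsampling of
  the coefficient map, which multiplicatively gates the skip before it is
  *added* to the upsampled decoder features. The gated-additive combination
  (rather than concatenation) keeps the skip path additive, which is the
  design the attention mechanism replaces, and halves the finest-level
  convolution cost.
* **Switchable normalization** at every normalization site: a learnable
  softmax mixture over instance, layer and batch statistics. With batch size
  1 — the pipeline's setting, to handle heterogeneous crop shapes — the batch
  branch's statistics coincide with the instance branch's; the three mixture
  weights remain learnable and sum to 1.
* **Softmax head** over the canonical classes (background, DG, CA1, CA2,
  CA3, SUB, optionally HEAD/TAIL).

Input dimensions must divide `2^(depth − 1)` (one halving per level below the
finest); padding to multiples of 8 guarantees this for depths up to 4.

The network, reverse-mode autodiff tape, AdamW, the one-cycle schedule and
stochastic weight averaging are implemented in the package. Convolutions run
in single precision through BLAS (a shift-GEMM scheme for the dominant
3×3×3/stride-1 case); everything else is double. Gradients are verified
against finite differences in the test suite.

## The loss

The base loss per class is the focal Tversky loss on soft confusion counts
(sums of probability mass, no argmax — required for differentiability):

`L_c = (1 − TP_c / (TP_c + β FN_c + α FP_c))^γ`, with α = 0.3, β = 0.7
weighting false positives and false negatives asymmetrically. The focal
exponent defaults to γ = 0.75; both 3/4 and 4/3 are plausible focal-Tversky
exponents, so γ is an explicit configuration knob rather than a hidden
constant. With α = β = 0.5 and γ = 1 the loss reduces exactly to
one-minus-soft-Dice, which the tests exploit as an independent oracle. For
γ < 1 the gradient of `b^γ` diverges as `b = 1 − TI → 0`; the backward pass
clamps `b` at 1e-6 (loss values are exact; only the gradient at essentially
perfect predictions is bounded).

Per-observation protocol modulation: merge groups sum the probability
channels of classes the rater did not distinguish (e.g. CA2+CA3); with a
head/tail protocol, subfield probability mass inside head/tail target voxels
is pooled into that cap's channel — a subfield prediction there counts as a
true positive of "hippocampus", not a false positive — and subfield channels
are zeroed inside the caps, all as a voxelwise linear (hence exactly
differentiable) map. Classes absent from an observation's ground truth are
skipped in the class mean rather than scored 0, so absent classes can neither
inflate nor deflate the loss. Background is an ordinary channel.

## Training

Bagging: each of E weak learners (default 5; desk benchmark 2) trains on N
draws with replacement from the training set (seeds `seed + 1 … seed + E`).
Each step consumes one observation (batch size 1), with AdamW (decoupled
weight decay 1e-4 on convolution weights only), a one-cycle learning rate
(linear warmup over 30% of steps to `peak_lr`, default 5e-3, then cosine
annealing to 0) and stochastic weight averaging: parameters are averaged over
epoch-end snapshots from 75% of training onward. Training is deterministic
given the master seed. Training-time augmentation reuses the TTA transform
family (a fresh random flip/affine/elastic per step, drawn from per-step
seeds, so determinism is preserved) and is on by default: with bags of ~13
unique phantoms and 40 epochs, unaugmented members memorize their bag
(training loss below 1e-3) and lose subfield accuracy on held-out
geometries, while augmented members generalize. Disable it
(`train_config(augment = FALSE)`) for single-sample capacity checks such as
the overfit sanity test.

Magnitude pruning zeroes the globally smallest-magnitude convolution weights
to a target sparsity (default 70%); biases and normalization parameters are
untouched.

## Inference

Each crop is augmented into `n_versions` copies (default 21): version 1 is
the identity — so degenerate configurations reduce exactly to a single
model's argmax — and the rest draw a horizontal flip (p = 0.5), a small
affine (rotations ±10°, isotropic scale 0.95–1.05) and an elastic
deformation (4³ control grid, ±2 voxel displacements, trilinearly
upsampled). Predictions are mapped back to native crop space before voting:
flips and affines are inverted exactly, elastic warps via the
negated-displacement approximation (the residual is checked in tests, and is
the standard approximation for small smooth fields). Voting across unaligned
augmentations would be meaningless.

The fused label is the voxel-wise plurality vote over all E × n_versions
realigned predictions, ties broken toward the lowest class id
(deterministic, documented). The uncertainty map is the Shannon entropy of
the per-voxel vote frequencies — 0 under unanimity, at most log(number of
classes). Although often labelled "aleatoric", this quantity mixes
test-time-augmentation and ensemble variation; the package documents it as
vote entropy.

## Metrics

Dice and volumetric similarity follow their standard forms; VS is the
volume-only form `1 − ||ym| − |yp|| / (|ym| + |yp|)` (a printed formula with
an intersection term would contradict the definition of a volume comparison,
so the prose definition wins). The Hausdorff distance is computed between
voxel-center point sets of the *full* masks, matching the printed definition;
a surface-only variant is available behind `surface = TRUE` but off by
default, and distances are reported in physical units whenever spacing is
known. All three are validated against brute-force oracles, exhaustively on
all 2⁹ masks of a 3×3 plane for DC and VS.

## Lifespan analytics

Volume trajectories are modelled per sex as natural cubic splines of age
fitted by OLS (`splines::ns` basis: quantile-placed interior knots, linear
beyond the boundary knots), with degrees of freedom selected by AIC over
2–15 (ties to the smallest df). Inflection ages are detected with the
kneedle procedure on the fitted curve evaluated on a 0.5-year grid with
sensitivity 1.0, applied separately to the rising and falling segments split
at the curve's global maximum so both the growth-end and decay-onset knees
are found; each segment is normalized to the unit square, decreasing or
convex shapes are flipped onto the concave-increasing case, and the knee is
the maximum of the difference-from-chord curve when it clears the
sensitivity threshold. A fitted straight line yields no inflections.

Periods are the intervals between consecutive inflection ages (per region,
the per-sex detections merged when within 5 years, plus the age-range
boundaries). Within each period — where the trajectory is assumed linear —
`volume ~ age * sex` is fitted by OLS, and p-values for the age slope, sex
effect and interaction are corrected with Benjamini–Hochberg FDR over the
family of all regions and terms of one analysis. Single-sex tables drop the
sex terms and still estimate the age slope.

The cohort generator builds its noiseless curves as natural interpolating
splines through control points on a growth–plateau–decay skeleton, with
symmetric control points 4 years on either side of each knot so the curve
bends *at* the stated knot ages; defaults place growth end at 22 and decay
onset at 70 with plateau volumes of the order of adult subfield volumes,
a +5% male plateau offset and 1.3× male slopes, and residual sd of 5% of the
plateau. With 1000 subjects per sex these settings make the decay-onset knee
recoverable to within about ±3 years — the kneedle knee of a smoothed corner
sits slightly after the true onset, since it marks the point where the
fitted slope reaches the chord slope, which is the dominant residual bias.

The anteroposterior profile tabulates, per slice along a declared axis
(default the second voxel axis; never auto-guessed), the fraction of each
subfield among hippocampus voxels, normalizes slice positions to 0–100%
between the first and last non-empty slices, resamples to a common grid and
averages across subjects.

## Problem sizes and runtimes

The tested desk configuration trains two weak learners (depth 3, 8 base
channels) for 40 epochs on twenty 32³ phantoms and evaluates on ten held-out
phantoms with 5-version TTA — about 12 minutes on one CPU — and reaches mean
per-class Dice above 0.8 with boundary vote entropy exceeding interior vote
entropy. Full-scale settings (depth 4, 5 members, 512 epochs, 21 TTA
versions) remain available through the same configuration objects.

## Known limitations

* The built-in registration handles rigid/affine mono-modal alignment only;
  real-MRI use should plug in a dedicated registration tool.
* Elastic TTA inversion is approximate; a small fraction of boundary voxels
  realign imperfectly and surface as boundary uncertainty.
* The phantom's subfield arrangement is an idealized angular partition, not
  hippocampal anatomy; per-class Dice on phantoms says nothing about
  protocol fidelity on real scans.
* Vote entropy is not calibrated against error rates and mixes augmentation
  with ensemble disagreement.
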