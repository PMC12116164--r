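---
title: "Apple yield estimation from fused canopy, spectral and chlorophyll features: models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apple yield estimation from fused canopy, spectral and chlorophyll features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardyield)
```

## The estimation problem

Orchard yield forecasting at the plot scale benefits from combining three
complementary views of a tree stand: *how much reproductive structure* the
trees carry (flowers in spring, bagged young fruit in early summer), *how
vigorous* the canopy looks from above (vegetation indices from 4-band
reflectance), and *how photosynthetically active* the leaves are (SPAD
chlorophyll readings). Each source alone is an incomplete proxy; the
package's purpose is to extract all three per plot and fuse them in a
regression model of plot yield (kg).

## Segmentation model

Structural features come from semantic segmentation of tree photographs
taken against a white backdrop. The network is a DeepLabv3+-style
encoder–decoder with two attention insertions:

* a **CBAM** block on the final encoder feature map, before ASPP. Channel
  gate: `σ(MLP(avgpool) + MLP(maxpool))` with a shared two-layer MLP
  (reduction ratio 16 by default); spatial gate: `σ(conv7×7([mean_c; max_c]))`.
* an **ECA** block on the stride-4 low-level path, immediately before the
  decoder concatenation. The 1-D kernel length adapts to the channel count
  as the nearest odd integer to `|log2(C)/γ + b/γ|`, with `γ = 2`, `b = 1`
  (so `k = 5` at 256 channels, `k = 3` at 16–32 channels).

Both gains are sigmoids, hence strictly inside (0, 1): attention can only
attenuate, never amplify, and output shapes are preserved. One numerical
remark: "equal channels in, equal gains out" holds for ECA wherever the
kernel support sees identical neighbors (everywhere for `k = 1`, away from
the zero-padded ends otherwise), and for CBAM exactly when its MLP weights
are channel-symmetric — the MLP mixes channels, so arbitrary weights break
the symmetry. The test suite asserts the property in this exact form.

The backbone is deliberately small — a residual encoder at output stride
16 with default widths 12/16/24/32 — because the architectural contribution
being exercised is the *attention placement*, not encoder capacity, and the
whole network (forward and backward) is implemented natively in R. The
encoder, ASPP (1×1 branch, three dilated 3×3 branches at rates 2/4/6 by
default, and an image-pooling branch), decoder and both attention blocks
are trained end-to-end; gradient correctness is enforced by a finite-
difference check in the test suite. Every convolution that feeds a batch
normalization is bias-free, the standard redundancy elimination.

Training choices where the problem statement is silent: pixel-wise
cross-entropy with uniform class weights, SGD with momentum 0.9, polynomial
learning-rate decay (power 0.9, the family standard) with a constant-rate
option, and no data augmentation. Batch statistics use running estimates
(momentum 0.1) at inference. The canonical field-scale regime — 300 epochs,
batch 8, learning rate 0.01, 4:1 train/test split — is the `train_config()`
default; desk-scale runs in the tests and acceptance script use eight
128×128 scenes, a learning rate of 0.1 and at most 200 full-batch steps,
which this small network needs to overfit its training scenes to
mIoU ≥ 0.9 within about two minutes on one CPU. Those sizes are a
deliberate choice to keep the demonstration self-contained and fast; they
say nothing about field-scale accuracy.

Metrics: PA = trace/total of the confusion matrix; AccClass = mean
per-class recall over classes present in the truth; `IoU_c =
TP/(TP+FP+FN)`; mIoU averages IoU over classes present in either truth or
prediction — classes absent from both are excluded rather than scored 0/0.
mIoU ≤ PA is *not* an invariant and is not asserted.

## Canopy structure

Images are tiled (`tile_image()`, default 512 px, row-major from the
top-left). Partial edge tiles are padded white by default, with padded
pixels labeled background and excluded from pixel counts; alternatives are
reflection padding and dropping partial tiles. The background-tile screen
is programmatic: a tile is kept when at least 1% of its pixels fall below
the whiteness threshold (240) in some channel. Counts are pooled over
tiles (not averaged per tile) before ratios are formed, and the ratios are
therefore exactly invariant to the tiling — a tested identity. Degenerate
trees: a zero canopy total (SA or SB) raises an error; a zero numerator
returns a 0 ratio; a positive organ count with zero leaf pixels raises,
since the organ-to-leaf ratio is genuinely undefined. Plots photographed as
several trees aggregate as the mean of per-tree ratios.

## Spectral indices

Visible indices are computed on chromatic coordinates (`r+g+b = 1`
identity, enforced to 1e−12 in tests), which makes them invariant to
positive rescaling of the raw digital numbers — a brightness-robustness
property the normalization exists to provide. Zero denominators become
nodata per index, never NaN. GNDVI is implemented with the blue band,
`(NIR−B)/(NIR+B)`, matching the formula as printed in the source tables
this package follows; the common green-band variant is available via
`gndvi = "green"`. Four further indices that appear in the field literature
without a stated formula here (ExGR, RGBVI, GRVI, RVI) sit behind an
`extended` flag using their standard literature definitions and are
excluded from the default feature sets. The per-plot statistic is the mean
over valid pixels whose centers fall inside the plot polygon (no canopy
masking by default; an ExG-based mask is a reasonable extension for soil-
contaminated plots but is deliberately not applied silently).

## Yield fusion

Features are screened by Pearson correlation with yield using per-group
rules: SPAD and multispectral indices pass at |r| > 0.6, structural ratios
at |r| > 0.7, and only the single best visible index is taken. The rules
alone do not produce a unique canonical set — GNDVI can clear the
multispectral threshold yet stay out of the fused set — so the screen also
honors an explicit exclusion list (default: GNDVI). This is a documented
choice, not an inferred rule. The selected indices enter the record under
their aliases `d1` (DVI), `d2` (GDVI), `d3` (GEVI), `k1` (VARI).

Feature sets: A = {s1, s2}, B = {f1..f4}, C = {d1, d2, d3, k1}, D = A∪B,
E = B∪C, F = A∪C, G = A∪B∪C.

Models and defaults (the algorithm families are given, their
hyperparameters are this package's choices, all overridable): KNN with
k = 5; PLS with the component count chosen by 5-fold cross-validation on
the training split over `1..min(p, n−1)` — the search is not capped below
`p`, because on noise-free linear data only the full-rank solution recovers
the generative coefficients exactly, a property the tests assert to 1e−6;
random forest with 500 trees; RBF ε-SVR with ε = 0.01 and cost/γ selected
by a small cross-validated grid. KNN, PLS and SVM see z-score-standardized
features (fitted on the training split only); the forest runs unscaled.
The 7:3 split is a single seeded shuffle with the train size rounded half
up. Replication across seeds is how uncertainty is assessed; no interval
estimates are produced.

Shapley attribution is exact: the coalition value is the mean prediction
over a background set with coalition features taken from the explained row,
and attributions use the exact combinatorial weights over all `2^p`
coalitions. At p = 10 this is 1024 coalitions — cheap, and it gives a gold
standard satisfying efficiency, symmetry and the null-player axiom to
1e−9, which the tests verify. Above p = 15 the function refuses rather
than silently approximating.

## Synthetic orchard: what it does and does not emulate

The generator stands in for non-deposited field data. Its defaults were
fixed once, as plausible stand-ins, and are stated here as configuration,
not as claims about any real orchard:

* **Scenes**: white backdrop N(250, 2) clipped to [245, 255]; a recursive
  branch skeleton (trunk thickness 8% of the smaller image side, tapering
  by 0.6 per branching level); elliptical leaf blobs placed until a target
  coverage; organ discs with radius 9% of the smaller side ± 20% jitter.
  Z-order branch < leaf < flower/fruit, counts taken after compositing, so
  the pixel ledger is exact by construction. Flowering scenes contain no
  fruit label and vice versa; one unified 5-label space serves both stages
  so a single model handles the joint dataset.
* **Rasters**: band means affine in a latent vigor v ∈ [0, 1]
  (R: 0.30−0.18v, G: 0.12+0.10v, B: 0.10−0.04v, NIR: 0.30+0.45v), plus
  spatially correlated noise, clipped to [0, 1]. NIR and G rise with vigor,
  so NDVI-type indices are monotone in vigor by construction.
* **Plots**: SPAD affine in vigor (+N(0,1) noise), ratios logistic in
  vigor, index features taken from the band model at the plot's vigor; all
  feature noises are small relative to their vigor-driven ranges. Yield is
  `intercept + β·features + N(0, σ)` truncated at zero, with a default β
  scaled so 20-tree plots span roughly 150–500 kg and σ = 5 kg. Because
  every feature is monotone in one latent factor, the synthetic data have
  strong positive cross-correlations — deliberately, so that the Pearson
  screen and the fusion-vs-single-source comparison are actually exercised.

What passing tests on these data *show*: the formulas, training loop,
screening, fusion and attribution machinery are correct, and fusion
dominates single sources when yield genuinely depends on all three groups.
What they *do not show*: field-scale segmentation accuracy (real canopies
have occlusion, shadows, annotation error), realistic feature
distributions, or transferability of any fitted model. Scenes are
procedural shapes, not photorealistic renderings; occlusion-induced
annotation error and sensor optics are not modeled.

## Numerical choices and degenerate inputs

Argmax masks break exact logit ties toward the lowest label id. Bilinear
resampling uses half-pixel center alignment; its backward pass is the
exact adjoint. The ECA 1-D convolution zero-pads the channel axis.
Zero-variance targets make R² an error, not NaN. The zonal mean errors on
polygons containing no valid pixel centers. `filter_background_tiles`
evaluates all tile pixels including white padding, which is consistent
with its purpose of discarding backdrop. Seeds: every stochastic entry
point takes an explicit seed and restores the caller's RNG state, so
identical configurations are bit-reproducible (the end-to-end report is
byte-identical across runs up to its timestamp).

## Known limitations

* The native R network trains small models on small images; it is a
  faithful, testable implementation of the architecture, not a performance
  substitute for GPU frameworks.
* The joint two-stage model is the default; per-stage training is possible
  by filtering scenes but is not specially supported.
* Exact Shapley is exponential in p; the deliberate p ≤ 15 cap means wide
  feature matrices need external approximation tools.
* Rasters are plain multi-band TIFFs in pixel coordinates; georeferenced
  workflows (CRS handling, reprojection) are out of scope.
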