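---
title: "Weakly-supervised emphysema subtyping: models, losses and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-supervised emphysema subtyping: models, losses and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emphysemap)
```

## The problem

The Fleischner Society's structured scoring system grades emphysema on chest
CT by subtype and severity: centrilobular emphysema (CLE) on a six-level
ordinal scale (absent, trace, mild, moderate, confluent, advanced
destructive) and paraseptal emphysema (PSE) on a three-level scale (absent,
mild, substantial). Each grade is defined by the fraction of the lung
involved, which makes the scale weakly quantitative: a CLE score of 1 means
that roughly 1-5% of the lung shows centrilobular destruction. Manual
scoring is slow and subjective; this package implements a deep-learning
pipeline that automates it while also producing a continuous per-lung
emphysema percentage for each subtype and a dense, voxel-level activation
map that shows *where* the network sees disease.

The central idea is to train with *interval regression* rather than plain
classification. The ordinal score of each training scan is converted into
the percentage interval it implies (`score_to_interval()`, the mapping in
`interval_table()`), and the network predicts a percentage directly. A
prediction inside the labelled interval costs nothing; outside, the penalty
grows quadratically:

$$K = \left(\tfrac{1}{2}(r_l - r_u)\right)^2,\qquad
L_{INT} = \max\!\left(0,\; \left(p - \tfrac{1}{2}(r_l + r_u)\right)^2 - K\right)$$

The percentage itself is the lung-wise mean of a sigmoid-activated,
single-channel dense map (the *dense regression activation map*), so the
per-scan supervision constrains a spatial field. Two further losses shape
that field:

* the **overlapping loss**, the soft Dice between the CLE and PSE maps
  $L_{OL} = 2\sum_i p_C^i p_S^i / (\sum_i p_C^i + \sum_i p_S^i)$, drives the
  two subtype maps apart, encoding the assumption that a voxel belongs to at
  most one subtype;
* the **segmentation loss**, a label-smoothed binary cross-entropy between
  the clamped joint map $p = \min(\max(p_C + p_S, 0), 1)$ and the LAA-950
  pseudo-label (lung voxels below -950 HU, the standard densitometric
  emphysema surrogate), ties the union of the maps to visibly destroyed
  tissue.

The total loss is the unweighted sum $L = L_{INT} + L_{OL} + L_{SEG}$ (one
interval term per subtype).

## Architecture

The backbone is a 3D ResNet (18, 34 or 50 layers; 34 is the default). A
$7^3$ stride-2 stem with 64 filters and a $3^3$ stride-2 max-pool are
followed by four ResNet layers with (2,2,2,2) blocks for ResNet18 and
(3,4,6,3) for ResNet34/50; ResNet50 uses bottleneck blocks. From layer 2 on
the first block doubles the channel count, and only layer 2 strides, so the
backbone output sits at 1/8 of the input resolution. Because 1/8-resolution
class-activation maps are too coarse for lesion localization, a
reconstruction network restores resolution: two stages of trilinear
$\times 2$ upsampling, each concatenating skip features from the backbone
stage of matching resolution (the layer-1 output at 1/4, the post-stem
features at 1/2) and applying two $3^3$ convolutions (each followed by batch
normalization and ReLU). Dense maps therefore live at 1/2 of the input
resolution. The heads are $1\times1\times1$ convolutions without
normalization: 6 + 3 channels with global average pooling and per-subtype
softmax for classification training, or 1 + 1 sigmoid channels with
lung-masked mean pooling for regression training. The two heads are
alternatives, not a multi-task pair.

The reconstruction channel widths are not something the original
description pins down; they are fixed here by the published trainable
parameter budgets of the three variants (34.48, 64.79 and 47.86 million).
With widths 576→64→64 and 128→50→32 (ResNet18/34) and 2304→24→64 and
128→39→32 (ResNet50), `count_params()` reproduces all three budgets at two
decimals, and the 32-channel head input also matches the published compute
difference between the classification and regression heads. Those counts
are asserted in the test suite:

```{r params, eval = FALSE}
count_params(build_network(network_config("resnet34", "regression")))
# 64,792,038 parameters = 64.79 M
```

A `width_mult` argument scales every channel width for desk-scale
experiments; `1/8` (stem width 8) is used throughout the package's phantom
studies. All tensors are R double arrays; the convolution kernels compute
in single precision (im2col + GEMM through RcppArmadillo), which matches
standard deep-learning practice and roughly doubles throughput, while batch
normalization, losses and the optimizer run in double precision.

## Preprocessing and pseudo-labels

CT volumes in HU are clamped to $[-1150, -300]$, rescaled affinely to
$[0, 1]$, cropped to the tight bounding box of the lung mask (no margin —
the source description says only that the lung segmentation is used for
cropping), resized with trilinear interpolation to the fixed network input
grid (default $128\times224\times288$; the grid is generally anisotropic
after this step), and masked so that voxels outside the lung are exactly
zero. The mask travels through the same trilinear resize and is
re-binarized at 0.5 so that image and mask edges agree. The LAA-950
pseudo-label is computed on the *raw* HU grid (the threshold is defined in
HU; -950 lies inside the clamp window, so either order would give the same
voxels) and transported to the dense-map grid with the same crop and zoom,
then re-binarized at 0.5. The crop box and zoom factors are stored as
provenance so that predictions and dense maps can be resampled back onto
the original CT grid exactly (`predict_scan()`, `export_maps()`).

## The phantom generator

Because the clinical cohort behind the published evaluation cannot ship
with a package, every end-to-end experiment here runs on synthetic
phantoms (`generate_phantom()`, `prepare_cohort()`). A phantom emulates
exactly the statistical structure the method relies on, and nothing more:

* two disjoint ellipsoids stand in for the lungs; parenchyma is sampled
  i.i.d. from $N(-850, 30)$ HU, so the probability that a healthy voxel
  falls below -950 HU is $\Phi(-10/3) \approx 4\times10^{-4}$ and
  pseudo-labels are effectively blob-driven;
* emphysema is inserted as spheres of $N(-1000, 15)$ HU tissue (radius 2-4
  voxels) — centrilobular blobs have centres deeper than a 4-voxel margin
  from the lung boundary (distance by exact Euclidean distance transform),
  paraseptal blobs have centres within that margin, mirroring the
  core-scattered versus subpleural presentation of the two subtypes;
* blobs are added greedily, rejecting any blob that touches the other
  subtype's mask, until the achieved LAA fraction of each subtype reaches
  its target (tolerance 0.01 by default); the *achieved* fractions, not the
  targets, define the truth labels, so labels are exactly consistent with
  the voxel data;
* cohorts draw (CLE, PSE) score pairs uniformly over the $6\times3$ score
  grid and per-phantom targets uniformly inside the drawn score's interval,
  with draws from the open-ended top intervals capped at 0.45 (CLE) and
  0.20 (PSE) — realistic severe-disease involvements that the spherical
  blob model can actually reach.

What phantoms do *not* model: airway and vessel trees, lobular texture,
scanner and reconstruction-kernel effects, gravity-dependent gradients, and
the correlation structure of real severity scores. Passing the phantom
recovery experiments therefore demonstrates that the pipeline — losses,
architecture, optimization, decoding — can recover subtype-resolved
emphysema burden from images whose labels are only ordinal, not that the
package reaches clinical-grade accuracy on real CT; the published
agreement statistics reproduced from the evaluation tables are the
clinical reference points.

The default phantom grid is $48\times64\times80$, the package's desk-scale
reference resolution: large enough that blobs survive the resize chain to
the dense grid, small enough that a full training run fits in minutes of
CPU time.

## Training

Training follows the published schedule: Adam, batch size 4 (implemented as
gradient accumulation over four single-volume passes; batch normalization
uses the spatial statistics of each volume, which are stable given the
$\sim10^5$ voxels per volume), exponential learning-rate decay of 0.9 per
epoch, early stopping after 10 epochs without validation improvement, and a
200-epoch ceiling. The validation metric is the mean of the centrilobular
and paraseptal linear weighted kappa on the validation split (ties broken
by lower validation loss); the best-validation parameter snapshot is what
`fit()` returns. For classification training, cross-entropy class weights
start at inverse label frequencies (normalized to mean 1) and are rescaled
after every epoch by $(1 - \mathrm{acc}_c + \delta)$ with $\delta = 0.1$, a
multiplicative form chosen here since only the goal — penalizing classes
with low per-class accuracy — is described in the source.

The published initial learning rate (1e-5) is tuned to full-scale training
(thousands of scans, hundreds of epochs, full-width network). At desk scale
a width-1/8 network seeing 150 phantoms for at most 30 epochs takes a few
hundred Adam steps in total, and 1e-5 cannot move it measurably; the
phantom experiments therefore use 1e-3 with decay 0.95. The `train_config()`
default remains the published schedule.

Augmentation (sagittal flips, in-plane rotations, crop-and-resize, Gaussian
smoothing, intensity/contrast jitter, additive noise) is applied jointly to
the image, the mask *and* the LAA pseudo-label for spatial transforms —
training targets must live on the same grid as the warped image. Parameter
ranges are package defaults (the source names the transform families but no
magnitudes); each transform fires independently with a configurable
probability, and validation volumes are never augmented. Label smoothing
uses $\varepsilon = 0.1$ ($t' = t(1-\varepsilon) + \varepsilon/2$) and the
segmentation smoothness factor defaults to $s = 1$; neither constant is
printed in the source, so both are configurable in `loss_config()`.

The smoothness factor matters greatly at desk scale. $L_{SEG}$ and $L_{OL}$
act per voxel and are indifferent to *which* head claims a lesion, while
the per-scan interval loss — the only force that attributes lesions to the
correct subtype — spreads its gradient uniformly over $\sim 10^4$ lung
voxels. With $s = 1$ and a few hundred optimizer steps, gradient descent
reliably falls into a subtype-entangled minimum: one sigmoid map absorbs
the whole LAA target, the other dies, and the overlap loss then acts as an
energy barrier against re-attribution (moving a lesion between heads must
pass through a high-overlap state). The desk-scale experiments therefore
use $s = 0.1$, which balances the per-voxel and per-scan terms so the weak
ordinal labels can drive subtype attribution within a 15-20-epoch budget;
full-scale training with orders of magnitude more scans and steps does not
need this rebalancing, which is presumably why the source leaves $s$
unspecified. The
segmentation loss is averaged over lung voxels (not summed) so its scale is
invariant to grid size; the overlap loss is computed over the whole dense
grid, where maps are near zero outside the lung by construction.

## Numerical choices and edge cases

* Interval bounds use a closed-lower/open-upper convention; a percentage
  exactly on a boundary takes the higher score and $p = 1$ belongs to the
  top score. The prose description of the mild grade conflicts with the
  published mapping table; the table governs.
* The overlap loss is defined as 0 when both maps are identically zero
  (guarded denominator).
* The joint map is clamped to $[0, 1]$ and clipped to
  $[10^{-7}, 1-10^{-7}]$ before the logarithm; the clamp contributes a zero
  subgradient outside the open unit interval.
* Trilinear resampling uses half-pixel-centre sampling with edge clamping,
  so resizing to the native shape is the identity and preprocessing is
  idempotent at the input shape.
* Weighted-kappa confidence intervals use the Fleiss-Cohen-Everitt (1969)
  asymptotic variance; the original analysis names only an R package, and
  this estimator reproduces all published 95% intervals to well within
  0.02 on the kappa x 100 scale.
* One published confusion matrix (regression network, centrilobular) is
  internally inconsistent: one row disagrees with the printed marginals,
  recall and accuracy. The shipped fixture uses the count-consistent
  transcription (113 where the table prints 112), and tests assert
  count-derived statistics for the three quantities where print and counts
  disagree.

## Known limitations

* Training is single-device CPU; bit-reproducibility holds for a fixed
  seed on one platform but not across BLAS builds.
* The phantom task is easier than clinical scoring: blobs are homogeneous,
  spatial priors are clean, and no other pathology competes for the
  network's attention. Desk-scale agreement statistics are accordingly
  optimistic relative to the published clinical values.
* Head specialization (which subtype map claims which lesion) is driven
  entirely by the interval loss acting through samples in which one subtype
  is absent; with few training scans and few epochs this force is slow, and
  runs that are stopped too early can leave the subtype attribution
  entangled even when the joint emphysema burden is already accurate. The
  recovery experiments size the cohort and epoch budget so the validation
  kappa, not wall-clock, decides when to stop.
* The classification head is provided and tested, but the package's
  recovery experiments focus on the regression head, which is the method's
  distinctive contribution.
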