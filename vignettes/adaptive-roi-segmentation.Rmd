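---
title: "Adaptive-ROI lung nodule segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-ROI lung nodule segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleseg)
```

## The problem

Measuring a pulmonary nodule requires a volumetric mask, but radiologists
and CAD detectors naturally produce a single 2D region of interest (ROI) on
one axial CT slice. `noduleseg` turns that single seed into a full 3D
segmentation in two stages:

1. **Axial stage.** A dual-encoder segmentation network segments the seed
   slice given the slice and the seed ROI mask. The adaptive-ROI (A-ROI)
   rule then derives an ROI for the next slice from the current
   segmentation, and the loop marches up and then down the z axis until a
   derived ROI comes back blank — the sign that the nodule has ended.
2. **Multi-view stage.** The stacked axial mask seeds per-plane ROIs for
   every sagittal and coronal plane it touches; the network re-segments
   those views, and a per-voxel vote over the three view masks (threshold
   $\tau$ of $K = 3$) gives the final mask.

The guiding idea is that no cropping or resizing happens anywhere: the
network always sees full slices at native (resampled) resolution, with the
ROI supplied as an explicit second input — *hard* attention — rather than
by cutting out a patch whose rescaling would distort the boundary.

## Preprocessing

**Windowing.** Raw intensities are mapped to $[0,1]$ with the standard CT
display-window transform: with centre $WC$ and width $WW$,
$W_{min} = WC - WW/2$, $W_{max} = WC + WW/2$ and
$I_n = \mathrm{clip}\!\left(\frac{I - W_{min}}{W_{max} - W_{min}}, 0, 1\right).$
The clip implements the grayscale thresholding that suppresses tissue
outside the window. Missing window metadata is a hard error naming the
absent tag, since silently guessing a window changes every downstream
intensity.

**Isotropic z-resampling.** Clinical slice thickness (0.45–5 mm) usually
exceeds pixel spacing (< 1 mm), which squashes nodules in sagittal and
coronal views. The volume is therefore upsampled along z to the pixel
spacing before anything else; the in-plane grid is untouched. New slice $k$
samples old coordinate $(k-1)\,p/z_{mm} + 1$, so integer-ratio upsampling
reproduces every original slice exactly — a property the test suite pins
down, because it makes the interpolation auditable. Intensities are
interpolated linearly, masks by nearest neighbour (they must stay binary).
Downsampling is deliberately refused (warning, no-op): the pipeline only
ever increases z-resolution.

**Training samples.** For each nodule, every axial slice intersecting it
becomes a sample whose ROI input is the ground-truth bounding box dilated
by an independent uniform integer margin in $[1, 10]$ px per side. The
random margins prevent the network from learning a fixed box-to-boundary
offset. Two nodule-free slices on each side are added with an all-zero
target (reusing the nearest nodular slice's ROI) so the network learns
what nodule *absence* inside an ROI looks like — this is what lets a blank
segmentation terminate the axial march. The flanking-ROI reuse is a package
choice: the alternative (fresh random boxes) would also be defensible, but
reuse matches what the propagation loop sees at inference, where the ROI of
the first empty slice always comes from the last nodular one.

## The network

Two identical convolutional encoders ingest the slice and the binary ROI
mask; one decoder fuses them. Each encoder level is
`conv 3×3 → ReLU → batch norm → 2×2 max pool`, with $32n^2$ filters at
level $n$ (32/128/288/512) before width scaling — the quadratic ladder is
the default, with the conventional doubling ladder (32/64/128/256)
available as `filter_rule = "doubling"`. Each decoder level concatenates
the matching-level features of both encoders with the previous decoder
output, then applies `conv 3×3 → ReLU → batch norm → 2× nearest upsample`;
the last level replaces the upsample with a single-filter 1×1 convolution.
Because one output channel makes a softmax degenerate, the head is a
logistic (sigmoid) unit — the same intent, non-degenerate. The network is
fully convolutional: any input whose sides divide by $2^4$ works at
inference, and smaller slices are zero-padded to the next multiple.

Training minimises the soft dice loss
$L = \frac{1}{N}\sum_i \left(1 - \frac{2\sum p_i t_i + \varepsilon}
{\sum p_i + \sum t_i + \varepsilon}\right)$
with plain SGD (learning rate 0.001, momentum 0.9, batch 8) and early
stopping at patience 10 on the validation loss, returning the
best-validation weights. Four numerical choices matter in practice and are
therefore fixed and documented:

* **Loss smoothing $\varepsilon = 1$ during training.** With a near-zero
  $\varepsilon$ the numerator of an empty-target sample collapses to
  $\varepsilon$ and its gradient all but vanishes — the network would
  receive no signal at all from the nodule-free flanking slices, which are
  included precisely so it learns to output nothing when no nodule is
  present (and whose blank output terminates the axial march). The
  conventional smooth-by-one makes those samples actively push predictions
  toward zero. The *metric-side* `dice_loss()` keeps a negligible
  $\varepsilon$ so that it complements the dice score exactly.

* **Output bias initialised to −2.** Dice loss on heavily imbalanced masks
  has a weak early gradient when the network starts at $p \approx 0.5$
  everywhere (the denominator is huge). Starting near "background
  everywhere" is the standard remedy and markedly shortens the burn-in.
* **Batch-norm running-statistic momentum 0.9.** Validation is scored in
  eval mode from running statistics; with only a few dozen batches per
  epoch at desk scale, the common 0.99 would lag the weights by many
  epochs.
* **Binarisation threshold 0.5**, configurable; probabilities are
  thresholded per slice and, as a hard-attention guarantee, pixels outside
  the ROI's bounding box are forced to zero in the binary mask. The second
  encoder usually enforces this on its own, but the propagation loop
  requires *certainty* that masks stay spatially bounded, so the contract
  is enforced at the output too.

The engine itself (im2col convolutions on BLAS, batch norm, pooling,
backprop) is part of the package, with the convolution kernels in C++;
the gradient of every layer is verified against central finite differences
in the test suite.

## The adaptive-ROI rule

Given a slice segmentation, the next ROI is the tight bounding box of the
mask — covering *all* connected components, since lobulated nodules may
fragment at threshold — expanded on each side of each dimension by
$\lceil r_t \cdot \text{extent} \rceil$ pixels and clipped to the image.
The box thus re-centres on the nodule and scales with it. $r_t \in (0,1)$
defaults to 0.3: small enough that neighbouring vessels rarely enter the
box, large enough that a nodule's cross-section can grow slice-to-slice
without escaping. The ceiling guarantees at least one pixel of margin even
for tiny cross-sections. This margin rule is a definition made by this
package (the behaviour "re-position and re-size" admits several concrete
rules); it is isolated behind `roi_from_segmentation()` so alternatives
can be plugged in without touching the propagation loop.

An empty segmentation maps to an all-zero ROI — the loop's termination
signal, never an error. Termination is structural: each step moves one
slice monotonically, the volume is finite, and a blank ROI stops the
march, so the visit count per direction is at most `n_slices + 1`.

## Stage 2 and the consensus

Sagittal and coronal ROIs come from the axial mask's cross-sections run
through the *same* margin rule — one mechanism, reused. Stage 2 visits
exactly the planes the axial mask touches, with no propagation: the axial
stage has already established the nodule's extent, and letting the other
views wander would reintroduce the drift the vote is meant to cancel. All
views are segmented on the isotropically resampled volume so the nodule's
aspect ratio is preserved.

The vote is strictly binary: voxel $i$ enters the final mask iff
$\sum_{j=1}^{K} S_{ij} \ge \tau$. $\tau$ is selected on validation data by
scanning $\{1, \dots, K\}$ for the best mean dice — dice because it is the
headline metric of the whole task — with ties broken towards the stricter
threshold. $\tau = 1$ is the union of views, $\tau = K$ the intersection,
and the masks nest monotonically in between, which the tests assert
exhaustively.

## Metrics and reference masks

Dice is implemented as $2|Y' \cap Y| / (|Y'| + |Y|)$. A union-denominator
variant circulates in print; it equals the standard form only for
identical or disjoint masks and breaks the harmonic-mean identity
$DSC = 2 \cdot SEN \cdot PPV / (SEN + PPV)$, so the standard form is the
default and the variant is kept behind `variant = "union"` for comparison
only. Both-empty dice is defined as 1 and flagged (`degenerate`
attribute); sensitivity with an empty reference and PPV with an empty
prediction are NA with the same flag, never silent zeros. Multi-reader
references use the 50%-consensus rule: a voxel is foreground when at least
$\lceil m/2 \rceil$ of $m$ annotators marked it (2 of 4 in the standard
four-reader setting). Summaries report mean ± sample standard deviation
($n-1$; a single case reports sd 0 with a flag).

## The phantom generator

Real thoracic CT with multi-reader annotations cannot ship with a package,
so every algorithmic claim is exercised on synthetic phantoms built to
stress exactly the features the pipeline relies on:

* anisotropic spacing, default $(2.0, 0.7, 0.7)$ mm — so z-resampling has
  real work to do;
* a bright lobulated ellipsoid (rotatable, boundary modulated by a
  low-order spherical harmonic) as the nodule, intensity −100 HU-like
  against a −600 background, with window metadata calibrated so
  normalisation lands background near 0.3 and nodule near 0.8;
* tubular vessel-like distractors anchored on the nodule surface at
  intermediate intensity (−300), plus smooth low-frequency texture and
  additive Gaussian noise (σ = 20);
* four simulated annotators, each flipping boundary-shell voxels with
  probability 0.15, feeding the 50%-consensus machinery.

All randomness derives from the spec's seed; the same spec renders
bit-identical scenes. With noise, vessels and texture switched off, the
nodule is the only structure above the window midpoint, so a 0.55
intensity threshold is an *exact* oracle segmenter. That oracle is what
lets the propagation loop, the multi-view reslicing and the consensus be
tested for exact recovery (dice 1.0) completely decoupled from learning.

What the phantoms do **not** emulate: juxtapleural and juxtavascular
attachment geometry, beam hardening, real HU calibration, reader-specific
bias (simulated jitter is unbiased), and the long-tailed shape diversity
of real nodules. A model scoring well here demonstrates that the
*machinery* is correct and learnable, not clinical-grade accuracy.

## Desk-scale study conditions

The bundled end-to-end experiment — also what `scripts/acceptance.R`
reruns — uses 20 phantom cases of $64^3$ voxels split 8/1/11
(train/validation/test, the 40/5/55 convention), a width-scale 0.25
network at 64×64 input, and the training recipe above capped at 50 epochs.
These sizes were chosen so the whole cycle (generate, train, segment,
evaluate) completes in minutes on a single CPU core while leaving the
optimiser settings untouched; the full-size geometry (512×512, width scale
1) is available through `dehanet_config`. At this scale the three views
share one set of trained weights: axial slices of the isotropically
resampled phantom are statistically exchangeable with sagittal and coronal
ones, so per-view training would triple the cost for little benefit.
Independent per-view models remain available by passing a named segmenter
list.

A candid note on variance: fifty CPU epochs is far short of convergence
for this architecture, and the quality of the resulting net — in
particular how strongly it over-segments inside large ROI boxes, which the
A-ROI feedback then amplifies — varies noticeably with the dataset and
initialisation seed. In runs we examined, the mean held-out consensus dice
ranged from roughly 0.48 (a poorly converged net whose axial stage
ballooned on every case) to 0.88; the strict vote selected on validation
($\tau = 3$, the intersection of views) is what keeps the consensus
usable even when the axial stage degrades. The bundled test suite pins one
fully seeded configuration and its result; `scripts/acceptance.R` reports
whatever its `--seed` produces, without cherry-picking.

## Known limitations

* The A-ROI margin rule is a definition, not a reconstruction of any
  particular prior implementation; published variants (fixed pixel
  margins, area ratios) can be swapped in behind the same interface.
* Stage 2 cannot extend the nodule beyond the stage-1 extent (by design);
  a stage-1 undershoot along z propagates into every view.
* The multi-head reading of the architecture — a decoder that also emits
  next/previous-slice ROIs directly — is noted but not implemented; the
  propagation loop derives ROIs from the segmentation mask instead, which
  keeps the ROI mechanism inspectable.
* DICOM series are not read directly (window centre/width must be supplied
  alongside NIfTI input or via a JSON sidecar).
* Training is single-threaded CPU SGD; it is meant for desk-scale
  experiments and correctness auditing, not for training clinical models.
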