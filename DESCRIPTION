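Package: noduleseg
Title: Two-Stage Lung Nodule Segmentation with Adaptive ROI Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Volumetric segmentation of pulmonary nodules in thoracic CT from
    a single user-supplied 2D region of interest. A dual-encoder
    hard-attention convolutional network segments one axial slice given the
    slice and a binary ROI mask; an adaptive-ROI algorithm re-derives the ROI
    for neighbouring slices from the current segmentation and propagates
    bidirectionally along the axial axis to build a 3D mask. The axial mask
    then seeds per-slice ROIs for sagittal and coronal re-segmentation, and a
    per-voxel thresholded vote over the three view masks yields the final
    nodule mask. Includes CT window-based intensity normalisation, z-axis
    isotropic resampling, dice-loss training with SGD and early stopping, a
    synthetic CT phantom generator with simulated annotator variability, and
    overlap metrics (dice, sensitivity, positive predictive value) with a
    50-percent annotator-consensus ground-truth builder.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    withr,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
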