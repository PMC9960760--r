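#' Window-based intensity normalisation
#'
#' Rescales raw CT intensities to \eqn{[0, 1]} using the volume's display
#' window: with \code{wmin = wc - ww/2} and \code{wmax = wc + ww/2}, each
#' voxel becomes \code{clip((I - wmin) / (wmax - wmin), 0, 1)}. Intensities
#' below the window floor map to 0 and above the ceiling to 1, suppressing
#' structures outside the soft-tissue/lung range of interest.
#'
#' @param volume A \code{\link{ct_volume}} whose \code{window} field is set.
#' @return A \code{ct_volume} with voxels in \eqn{[0, 1]}, same spacing,
#'   window retained.
#' @examples
#' v <- ct_volume(array(seq(-1000, 400, length.out = 8), c(2, 2, 2)),
#'                spacing = c(1, 1, 1), window = window_spec(-400, 1500))
#' range(normalize_window(v)$voxels)
#' @export
normalize_window <- function(volume) {
  if (!inherits(volume, "ct_volume")) stop("volume must be a ct_volume")
  w <- volume$window
  if (is.null(w))
    stop("volume has no window metadata (WindowCenter/WindowWidth absent); ",
         "attach one with window_spec()")
  out <- (volume$voxels - w$wmin) / (w$wmax - w$wmin)
  out[out < 0] <- 0
  out[out > 1] <- 1
  ct_volume(out, volume$spacing, w)
}

#' Isotropic resampling along the z axis
#'
#' CT slice thickness usually exceeds in-plane pixel spacing, squashing the
#' nodule in sagittal/coronal views. This upsamples the volume along z until
#' the slice spacing equals the in-plane pixel spacing, leaving the in-plane
#' grid untouched. The new slice count is \code{round(nz * z_mm / xy_mm)};
#' new slice \code{k} samples the old z coordinate
#' \code{(k - 1) * xy_mm / z_mm + 1} (so for integer ratios every original
#' slice is reproduced exactly), with linear interpolation between
#' neighbouring slices for intensities and nearest-neighbour for masks.
#'
#' @param volume A \code{\link{ct_volume}}. The y and x spacings must match
#'   (isotropic in-plane grid).
#' @param order Interpolation: \code{"linear"} (intensities, default) or
#'   \code{"nearest"} (binary masks, keeps values binary).
#' @return A \code{ct_volume} with \code{spacing = (xy, xy, xy)}. If the
#'   z spacing is already at (or below) the pixel spacing the volume is
#'   returned unchanged, with a warning when it is strictly below (the
#'   pipeline only ever upsamples).
#' @export
resample_z_isotropic <- function(volume, order = c("linear", "nearest")) {
  if (!inherits(volume, "ct_volume")) stop("volume must be a ct_volume")
  order <- match.arg(order)
  sp <- volume$spacing
  if (abs(sp[2] - sp[3]) > 1e-6 * max(sp[2], sp[3]))
    stop("in-plane spacing must be isotropic (y_mm == x_mm)")
  p <- sp[3]
  if (sp[1] < p - 1e-9) {
    warning("z spacing (", sp[1], " mm) already finer than pixel spacing (",
            p, " mm); volume returned unchanged")
    return(volume)
  }
  if (abs(sp[1] - p) <= 1e-9) return(volume)

  d <- dim(volume$voxels)
  nz_new <- as.integer(round(d[1] * sp[1] / p))
  # old (1-based) z coordinate sampled by each new slice, clamped at the top
  u <- pmin((seq_len(nz_new) - 1) * p / sp[1] + 1, d[1])
  out <- array(0, c(nz_new, d[2], d[3]))
  if (order == "nearest") {
    zi <- pmin(pmax(as.integer(round(u)), 1L), d[1])
    for (k in seq_len(nz_new)) out[k, , ] <- volume$voxels[zi[k], , ]
  } else {
    i0 <- pmin(floor(u), d[1])
    i1 <- pmin(i0 + 1, d[1])
    w1 <- u - i0
    for (k in seq_len(nz_new)) {
      out[k, , ] <- (1 - w1[k]) * volume$voxels[i0[k], , ] +
        w1[k] * volume$voxels[i1[k], , ]
    }
  }
  ct_volume(out, c(p, sp[2], p), volume$window)
}

#' Training ROI with random margins
#'
#' Builds the ROI-mask input used to train the segmentation network: the
#' tight bounding box of the ground-truth nodule mask, dilated independently
#' on each of the four sides by a margin drawn uniformly from
#' \code{margin_range} (integer pixels), then clipped to the image. Random
#' margins stop the network from keying on a fixed box-to-nodule distance.
#'
#' @param gt_mask 2D binary matrix with at least one foreground pixel.
#' @param margin_range Integer length-2 vector, inclusive bounds of the
#'   per-side margin draw (default \code{c(1, 10)} px).
#' @param seed Optional integer; when given, margins are drawn reproducibly
#'   without disturbing the caller's RNG stream.
#' @return Binary matrix of the same shape: 1 inside the dilated box.
#' @export
make_training_roi <- function(gt_mask, margin_range = c(1L, 10L), seed = NULL) {
  bb <- mask_bbox(gt_mask)
  if (is.null(bb)) stop("gt_mask is empty: training ROIs are only defined around nodules")
  margin_range <- as.integer(margin_range)
  if (length(margin_range) != 2L || margin_range[1] < 0 ||
      margin_range[2] < margin_range[1])
    stop("margin_range must be nondecreasing nonnegative integers")
  choices <- seq(margin_range[1], margin_range[2])
  draw <- function() choices[sample.int(length(choices), 4L, replace = TRUE)]
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  d <- dim(gt_mask)
  box_mask(d,
           max(1L, bb$r0 - m[1]), min(d[1], bb$r1 + m[2]),
           max(1L, bb$c0 - m[3]), min(d[2], bb$c1 + m[4]))
}

#' Build the per-slice training set for one nodule
#'
#' Emits one training sample per axial slice intersecting the nodule, plus
#' \code{n_flank} nodule-free slices on each side (where the volume extends
#' that far) so the network also learns nodule absence. Each sample carries
#' the normalised slice, an ROI mask from \code{\link{make_training_roi}},
#' the binary target, and an \code{is_nodular} flag; flanking slices reuse
#' the ROI of the nearest nodular slice and have an all-zero target.
#'
#' @param volume A normalised \code{\link{ct_volume}} (voxels in [0, 1]).
#' @param gt_mask3d Binary 3D array, same dimensions as the volume.
#' @param n_flank Nodule-free slices to include on each side (default 2).
#' @param margin_range Passed to \code{\link{make_training_roi}}.
#' @return List of samples, each a list
#'   \code{(image, roi_mask, target, is_nodular, z)}.
#' @export
sample_training_set <- function(volume, gt_mask3d, n_flank = 2L,
                                margin_range = c(1L, 10L)) {
  if (!inherits(volume, "ct_volume")) stop("volume must be a ct_volume")
  if (!identical(dim(volume$voxels), dim(gt_mask3d)))
    stop("volume and gt_mask3d dimensions differ")
  z_nod <- which(apply(gt_mask3d, 1, sum) > 0)
  if (length(z_nod) == 0L) stop("gt_mask3d is empty")
  z0 <- min(z_nod); z1 <- max(z_nod)
  nz <- dim(gt_mask3d)[1]

  rois <- list()
  for (z in z0:z1) {
    gt2 <- gt_mask3d[z, , ]
    rois[[as.character(z)]] <-
      if (sum(gt2) > 0) make_training_roi(gt2, margin_range) else NULL
  }
  # interior slices of a fragmented mask fall back to the nearest nodular ROI
  nearest_roi <- function(z) {
    zn <- z_nod[which.min(abs(z_nod - z))]
    rois[[as.character(zn)]]
  }

  zs <- seq(max(1L, z0 - n_flank), min(nz, z1 + n_flank))
  lapply(zs, function(z) {
    gt2 <- gt_mask3d[z, , ]
    nodular <- sum(gt2) > 0
    roi <- if (nodular) rois[[as.character(z)]] else nearest_roi(z)
    list(image = volume$voxels[z, , ],
         roi_mask = roi,
         target = if (nodular) gt2 else matrix(0, dim(gt2)[1], dim(gt2)[2]),
         is_nodular = nodular,
         z = z)
  })
}
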