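#' Adaptive-ROI parameters
#'
#' The single hyperparameter of the adaptive-ROI rule: the margin ratio
#' \code{rt} in (0, 1). When a new ROI is derived from a segmentation mask,
#' the mask's tight bounding box is expanded on each side of each dimension
#' by \code{ceiling(rt * extent)} pixels, where \code{extent} is the box
#' size in that dimension — so the box re-centres on the nodule and scales
#' with it.
#'
#' @param rt Margin ratio, strictly inside (0, 1). Default 0.3.
#' @return An \code{aroi_params} object.
#' @export
aroi_params <- function(rt = 0.3) {
  if (!is.numeric(rt) || length(rt) != 1L || rt <= 0 || rt >= 1)
    stop("rt must be a scalar in (0, 1)")
  structure(list(rt = rt), class = "aroi_params")
}

#' Axis-aligned ROI box on one slice
#'
#' @param axis One of \code{"axial"}, \code{"sagittal"}, \code{"coronal"}.
#' @param slice_index 1-based index of the slice along that axis.
#' @param lo,hi Integer (row, col) corners, 1-based inclusive,
#'   \code{lo <= hi} componentwise.
#' @return An \code{roi_box}.
#' @export
roi_box <- function(axis = c("axial", "sagittal", "coronal"), slice_index,
                    lo, hi) {
  axis <- match.arg(axis)
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 2L || length(hi) != 2L || any(lo < 1L) || any(hi < lo))
    stop("need 1 <= lo <= hi componentwise")
  structure(list(axis = axis, slice_index = as.integer(slice_index),
                 lo = lo, hi = hi),
            class = "roi_box")
}

roi_box_to_mask <- function(box, shape) {
  if (box$hi[1] > shape[1] || box$hi[2] > shape[2])
    stop("ROI box exceeds slice bounds")
  box_mask(shape, box$lo[1], box$hi[1], box$lo[2], box$hi[2])
}

#' Derive the next slice's ROI from a segmentation mask
#'
#' The heart of the adaptive-ROI algorithm: given the binary segmentation of
#' the current slice, produce the ROI mask to hand the segmenter on the
#' neighbouring slice. The tight bounding box of the mask (covering all
#' connected components) is expanded on each side by
#' \code{ceiling(rt * extent)} in that dimension and clipped to the image.
#' An empty segmentation yields an all-zero ROI — the propagation loop's
#' termination signal, not an error.
#'
#' @param seg Binary 2D matrix.
#' @param params An \code{\link{aroi_params}}.
#' @return Binary matrix of the same shape: a filled expanded box, or all
#'   zeros when \code{seg} is empty.
#' @examples
#' seg <- matrix(0, 48, 48); seg[21:30, 21:30] <- 1
#' bb <- which(roi_from_segmentation(seg, aroi_params(0.2)) > 0, arr.ind = TRUE)
#' range(bb[, 1])  # rows 19..32: margin ceiling(0.2 * 10) = 2 per side
#' @export
roi_from_segmentation <- function(seg, params = aroi_params()) {
  if (!inherits(params, "aroi_params")) stop("params must be aroi_params")
  bb <- mask_bbox(seg)
  d <- dim(seg)
  if (is.null(bb)) return(matrix(0, d[1], d[2]))
  mr <- ceiling(params$rt * (bb$r1 - bb$r0 + 1L))
  mc <- ceiling(params$rt * (bb$c1 - bb$c0 + 1L))
  box_mask(d,
           max(1L, bb$r0 - mr), min(d[1], bb$r1 + mr),
           max(1L, bb$c0 - mc), min(d[2], bb$c1 + mc))
}

#' Bidirectional axial ROI propagation
#'
#' Builds the stage-1 axial 3D nodule mask from a single seed ROI. The seed
#' slice is segmented with the seed ROI; then the loop marches slice by
#' slice towards increasing z, at each step deriving the next ROI from the
#' current segmentation via \code{\link{roi_from_segmentation}} and stopping
#' as soon as a derived ROI is blank (the nodule has ended) or the volume
#' boundary is passed; it then restarts from the seed segmentation and
#' marches towards decreasing z. Per-slice masks are stacked into a 3D
#' binary mask; unvisited slices stay zero.
#'
#' @param segmenter Anything with a \code{\link{segment_slice}} method.
#' @param volume A normalised \code{\link{ct_volume}}.
#' @param seed An axial \code{\link{roi_box}}, or a list
#'   \code{(slice_index, mask)} whose mask is reduced to its bounding box.
#' @param params An \code{\link{aroi_params}}.
#' @return A \code{nodule_mask3d} (see \code{\link{nodule_mask}}) with
#'   \code{source = "axial"} and attributes \code{trace} (per-slice JSON-able
#'   records: z, box, mask area) and \code{visits} (slices visited per
#'   direction, including the terminating blank one).
#' @export
propagate_axial <- function(segmenter, volume, seed, params = aroi_params()) {
  if (!inherits(volume, "ct_volume")) stop("volume must be a ct_volume")
  d <- dim(volume$voxels)
  shape2 <- d[2:3]
  if (inherits(seed, "roi_box")) {
    if (seed$axis != "axial") stop("seed must be an axial ROI")
    z0 <- seed$slice_index
    seed_mask <- roi_box_to_mask(seed, shape2)
  } else if (is.list(seed) && !is.null(seed$mask)) {
    z0 <- as.integer(seed$slice_index)
    bb <- mask_bbox(seed$mask)
    if (is.null(bb)) stop("seed ROI mask is empty")
    seed_mask <- box_mask(shape2, bb$r0, bb$r1, bb$c0, bb$c1)
  } else stop("seed must be an roi_box or list(slice_index, mask)")
  if (z0 < 1L || z0 > d[1]) stop("seed slice ", z0, " outside volume (1..", d[1], ")")

  out <- array(0, d)
  trace <- list()
  visits <- c(up = 0L, down = 0L)
  visit <- function(z, roi) {
    sg <- segment_slice(segmenter, volume$voxels[z, , ], roi)
    bb <- mask_bbox(roi)
    trace[[length(trace) + 1L]] <<- list(
      z = z, box = if (is.null(bb)) NULL else c(bb$r0, bb$r1, bb$c0, bb$c1),
      area = sum(sg$mask))
    sg$mask
  }
  seed_seg <- visit(z0, seed_mask)
  out[z0, , ] <- pmax(out[z0, , ], seed_seg)

  for (step in c(1L, -1L)) {
    dir <- if (step > 0L) "up" else "down"
    visits[dir] <- visits[dir] + 1L  # the seed slice counts in each sweep
    roi <- roi_from_segmentation(seed_seg, params)
    z <- z0 + step
    while (sum(roi) > 0 && z >= 1L && z <= d[1]) {
      sg <- visit(z, roi)
      visits[dir] <- visits[dir] + 1L
      out[z, , ] <- sg
      roi <- roi_from_segmentation(sg, params)
      z <- z + step
    }
  }
  structure(nodule_mask(out, source = "axial"),
            trace = trace, visits = visits)
}
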