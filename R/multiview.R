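#' Reslice the volume along a sagittal or coronal view
#'
#' Stage 2 of the pipeline re-examines the nodule in the two orthogonal
#' views. For every sagittal plane (fixed x) or coronal plane (fixed y) that
#' intersects the stage-1 axial mask, this extracts the resliced image
#' (rows = z, columns = y for sagittal, x for coronal) together with an ROI
#' mask derived from the axial mask's cross-section in that plane via the
#' same adaptive-margin rule used during propagation. Planes whose
#' cross-section is empty are excluded.
#'
#' @param volume A normalised, isotropically resampled
#'   \code{\link{ct_volume}}.
#' @param axial_mask3d Binary 3D array from stage 1, same dimensions.
#' @param axis \code{"sagittal"} or \code{"coronal"}.
#' @param params An \code{\link{aroi_params}} for the per-plane ROI margins.
#' @return A \code{view_stack}: list with \code{axis}, \code{planes}
#'   (volume indices of included planes), \code{slices}, \code{rois}, and
#'   \code{vol_dim}. Slice pixel (r, c) of plane p maps to volume voxel
#'   \code{(z = r, y = c, x = planes[p])} for sagittal and
#'   \code{(z = r, y = planes[p], x = c)} for coronal (see
#'   \code{\link{view_to_volume}}).
#' @export
extract_view <- function(volume, axial_mask3d, axis = c("sagittal", "coronal"),
                         params = aroi_params()) {
  axis <- match.arg(axis)
  if (!inherits(volume, "ct_volume")) stop("volume must be a ct_volume")
  d <- dim(volume$voxels)
  if (!identical(dim(axial_mask3d), d))
    stop("axial mask and volume dimensions differ")
  if (sum(axial_mask3d) == 0)
    stop("axial mask is empty: stage 1 found no nodule")

  take <- function(i) {
    if (axis == "sagittal") list(img = volume$voxels[, , i],
                                 cross = axial_mask3d[, , i])
    else list(img = volume$voxels[, i, ], cross = axial_mask3d[, i, ])
  }
  n_planes <- if (axis == "sagittal") d[3] else d[2]
  planes <- integer(); slices <- list(); rois <- list()
  for (i in seq_len(n_planes)) {
    sl <- take(i)
    if (sum(sl$cross) == 0) next
    planes <- c(planes, i)
    slices[[length(slices) + 1L]] <- sl$img
    rois[[length(rois) + 1L]] <- roi_from_segmentation(sl$cross, params)
  }
  structure(list(axis = axis, planes = planes, slices = slices, rois = rois,
                 vol_dim = d),
            class = "view_stack")
}

#' @export
print.view_stack <- function(x, ...) {
  cat(sprintf("view_stack [%s]: %d planes of %d x %d\n", x$axis,
              length(x$planes), nrow(x$slices[[1]]), ncol(x$slices[[1]])))
  invisible(x)
}

#' Map view-slice coordinates to volume coordinates and back
#'
#' @param stack A \code{view_stack}.
#' @param plane Index into \code{stack$planes}.
#' @param rc Length-2 (row, col) pixel within that view slice.
#' @return \code{view_to_volume}: length-3 (z, y, x) voxel index;
#'   \code{volume_to_view}: list \code{(plane, rc)} or NULL when the voxel's
#'   plane is not in the stack.
#' @export
view_to_volume <- function(stack, plane, rc) {
  i <- stack$planes[plane]
  if (stack$axis == "sagittal") c(rc[1], rc[2], i) else c(rc[1], i, rc[2])
}

#' @rdname view_to_volume
#' @param zyx Length-3 (z, y, x) voxel index.
#' @export
volume_to_view <- function(stack, zyx) {
  i <- if (stack$axis == "sagittal") zyx[3] else zyx[2]
  plane <- match(i, stack$planes)
  if (is.na(plane)) return(NULL)
  rc <- if (stack$axis == "sagittal") c(zyx[1], zyx[2]) else c(zyx[1], zyx[3])
  list(plane = plane, rc = rc)
}

#' Segment every slice of a view and scatter into volume coordinates
#'
#' Applies the segmenter to each view slice with its predefined ROI (no
#' ROI propagation in stage 2 — the planes to visit are fixed by the axial
#' mask) and writes the binary results back into a volume-shaped mask.
#' Voxels in planes the stack does not cover stay zero.
#'
#' @param segmenter Anything with a \code{\link{segment_slice}} method.
#' @param stack A \code{view_stack} from \code{\link{extract_view}}.
#' @return A \code{\link{nodule_mask}} in volume coordinates with
#'   \code{source = stack$axis}.
#' @export
segment_view <- function(segmenter, stack) {
  if (!inherits(stack, "view_stack")) stop("stack must be a view_stack")
  if (length(stack$planes) == 0L) stop("view stack is empty")
  out <- array(0, stack$vol_dim)
  for (p in seq_along(stack$planes)) {
    sg <- segment_slice(segmenter, stack$slices[[p]], stack$rois[[p]])
    i <- stack$planes[p]
    if (stack$axis == "sagittal") out[, , i] <- sg$mask else out[, i, ] <- sg$mask
  }
  nodule_mask(out, stack$axis)
}
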