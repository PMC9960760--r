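#' CT display-window specification
#'
#' A CT window is the linear intensity ramp used to map raw scanner
#' intensities to display/network range: the window centre \code{wc} and
#' width \code{ww} define the bounds \code{wmin = wc - ww/2} and
#' \code{wmax = wc + ww/2} between which intensities are rescaled to
#' \eqn{[0, 1]}.
#'
#' @param wc Window centre, in the volume's intensity units (e.g. HU).
#' @param ww Window width, same units; must be strictly positive.
#' @return An object of class \code{window_spec} with fields \code{wc},
#'   \code{ww}, \code{wmin}, \code{wmax}.
#' @examples
#' window_spec(wc = -400, ww = 1500)
#' @export
window_spec <- function(wc, ww) {
  if (!is.numeric(wc) || !is.numeric(ww) || length(wc) != 1L || length(ww) != 1L)
    stop("wc and ww must be numeric scalars")
  if (!is.finite(ww) || ww <= 0)
    stop("window width must be > 0, got ", ww)
  structure(
    list(wc = as.numeric(wc), ww = as.numeric(ww),
         wmin = as.numeric(wc) - as.numeric(ww) / 2,
         wmax = as.numeric(wc) + as.numeric(ww) / 2),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("CT window: centre %g, width %g  [%g, %g]\n",
              x$wc, x$ww, x$wmin, x$wmax))
  invisible(x)
}

#' CT volume container
#'
#' Bundles a 3D voxel array with its physical spacing and (optionally) the
#' display-window metadata needed for intensity normalisation. Voxels are
#' indexed \code{[z, y, x]} (axial slice first); all boxes and slice indices
#' in this package are 1-based with inclusive bounds.
#'
#' @param voxels Numeric 3D array, dimension \code{(nz, ny, nx)}.
#' @param spacing Numeric length-3 vector \code{(z_mm, y_mm, x_mm)}, all > 0.
#' @param window Optional \code{\link{window_spec}}.
#' @return An object of class \code{ct_volume}.
#' @export
ct_volume <- function(voxels, spacing, window = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (z_mm, y_mm, x_mm)")
  if (!is.null(window) && !inherits(window, "window_spec"))
    stop("window must be a window_spec or NULL")
  structure(list(voxels = voxels, spacing = spacing, window = window),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels (z, y, x), spacing %.3g/%.3g/%.3g mm%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (is.null(x$window)) ", no window" else
                sprintf(", window C%g/W%g", x$window$wc, x$window$ww)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti}. Spacing is taken from (written to) the
#' NIfTI \code{pixdim}; because this package indexes voxels \code{[z, y, x]}
#' while NIfTI stores \code{[x, y, z]}, the array is transposed on the way in
#' and out. Window metadata, which NIfTI does not carry, may be supplied via
#' a JSON sidecar \code{<file>.json} with fields \code{wc} and \code{ww}, or
#' as arguments.
#'
#' @param path Path to a NIfTI file (\code{.nii} or \code{.nii.gz}).
#' @param wc,ww Optional window centre/width overriding any sidecar.
#' @return \code{read_volume_nifti} returns a \code{\link{ct_volume}};
#'   \code{write_volume_nifti} returns \code{path} invisibly.
#' @export
read_volume_nifti <- function(path, wc = NULL, ww = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI image: ", path)
  pd <- RNifti::pixdim(img)  # (x, y, z)
  window <- NULL
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  if (is.null(wc) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$wc) && !is.null(meta$ww)) { wc <- meta$wc; ww <- meta$ww }
  }
  if (!is.null(wc)) window <- window_spec(wc, ww)
  ct_volume(aperm(arr, c(3, 2, 1)), spacing = rev(pd[1:3]), window = window)
}

#' @rdname read_volume_nifti
#' @param volume A \code{\link{ct_volume}} (or a plain 3D array with a
#'   \code{spacing} attribute-free mask, in which case \code{spacing} must be
#'   given).
#' @param spacing Spacing override when \code{volume} is a bare array.
#' @export
write_volume_nifti <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "ct_volume")) {
    arr <- volume$voxels; sp <- volume$spacing; win <- volume$window
  } else {
    if (is.null(spacing)) stop("spacing required when writing a bare array")
    arr <- volume; sp <- as.numeric(spacing); win <- NULL
  }
  img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(sp)
  RNifti::writeNifti(img, path)
  if (!is.null(win)) {
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
    jsonlite::write_json(list(wc = win$wc, ww = win$ww), sidecar,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

# ---- internal box helpers (1-based, inclusive) ------------------------------

# Tight bounding box of a nonempty 2D binary mask: list(r0, r1, c0, c1).
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(r0 = min(idx[, 1]), r1 = max(idx[, 1]),
       c0 = min(idx[, 2]), c1 = max(idx[, 2]))
}

# Filled-box binary mask of the given shape.
box_mask <- function(shape, r0, r1, c0, c1) {
  m <- matrix(0, shape[1], shape[2])
  m[r0:r1, c0:c1] <- 1
  m
}

as_binary <- function(x) {
  v <- unique(as.vector(x))
  if (!all(v %in% c(0, 1))) stop("mask must be binary (0/1)")
  x
}
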