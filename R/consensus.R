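#' 3D nodule mask with provenance
#'
#' @param mask Binary 3D array in volume coordinates (z, y, x).
#' @param source Which stage produced it: \code{"axial"},
#'   \code{"sagittal"}, \code{"coronal"} or \code{"consensus"}.
#' @return A \code{nodule_mask3d} object (the array, with \code{source}
#'   attribute and class).
#' @export
nodule_mask <- function(mask, source = c("axial", "sagittal", "coronal",
                                         "consensus")) {
  source <- match.arg(source)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  as_binary(mask)
  structure(mask, source = source, class = c("nodule_mask3d", class(mask)))
}

#' @export
print.nodule_mask3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("nodule_mask3d [%s]: %d x %d x %d, %d foreground voxels\n",
              attr(x, "source"), d[1], d[2], d[3], sum(x)))
  invisible(x)
}

#' Consensus-vote parameters
#'
#' @param k Number of models voting (default 3: axial, sagittal, coronal).
#' @param tau Vote threshold: a voxel enters the consensus mask when at
#'   least \code{tau} of the \code{k} models marked it. Integer in
#'   \code{[1, k]}.
#' @return A \code{consensus_params} object.
#' @export
consensus_params <- function(k = 3L, tau = 2L) {
  k <- as.integer(k); tau <- as.integer(tau)
  if (k < 1L) stop("k must be >= 1")
  if (tau < 1L || tau > k) stop("tau must be in [1, k]")
  structure(list(k = k, tau = tau), class = "consensus_params")
}

#' Per-voxel thresholded vote over aligned masks
#'
#' The consensus of \code{k} binary masks: output voxel \code{i} is 1 iff
#' \code{sum_j S_ij >= tau}. With \code{tau = 1} this is the union of the
#' masks, with \code{tau = k} their intersection.
#'
#' @param masks List of \code{k} aligned binary 3D arrays (or matrices).
#' @param params A \code{\link{consensus_params}}; \code{params$k} must
#'   equal \code{length(masks)}.
#' @return A \code{\link{nodule_mask}} with \code{source = "consensus"}
#'   (same-shaped binary array for 2D input).
#' @export
vote <- function(masks, params = consensus_params()) {
  if (!inherits(params, "consensus_params")) stop("params must be consensus_params")
  if (length(masks) != params$k)
    stop("expected ", params$k, " masks, got ", length(masks))
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d)) stop("masks are not aligned (shape mismatch)")
  tally <- Reduce(`+`, lapply(masks, function(m) {
    as_binary(m)
    unclass(m)
  }))
  out <- (tally >= params$tau) * 1
  if (length(d) == 3L) nodule_mask(out, "consensus") else out
}

#' Select the vote threshold on validation data
#'
#' Scans the integer grid \code{tau = 1..k}, scoring each by the mean dice
#' similarity of the consensus mask against ground truth over the
#' validation cases, and returns the best; ties break towards the larger
#' (stricter) threshold.
#'
#' @param val_cases List of validation cases, each a list with \code{masks}
#'   (list of \code{k} aligned binary masks) and \code{gt} (reference mask).
#' @param k Number of models.
#' @return The selected integer \code{tau}, with the per-threshold mean dice
#'   attached as attribute \code{"scores"}.
#' @export
select_tau <- function(val_cases, k = 3L) {
  if (length(val_cases) == 0L) stop("validation case list is empty")
  k <- as.integer(k)
  scores <- vapply(seq_len(k), function(tau) {
    mean(vapply(val_cases, function(case) {
      cm <- vote(case$masks, consensus_params(k, tau))
      dsc(cm, case$gt)
    }, numeric(1)))
  }, numeric(1))
  best <- max(which(scores == max(scores)))  # ties -> stricter threshold
  structure(best, scores = scores)
}
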