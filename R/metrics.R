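#' Overlap metrics: dice, sensitivity, positive predictive value
#'
#' For a predicted mask \eqn{Y'} and reference mask \eqn{Y}:
#' \itemize{
#'   \item \code{dsc}: \eqn{2|Y' \cap Y| / (|Y'| + |Y|)} — 1 means perfect
#'     overlap, 0 none. When both masks are empty the score is defined as 1
#'     (both agree nothing is there) and flagged via
#'     \code{attr(, "degenerate")}. The union-denominator variant
#'     \eqn{2|Y' \cap Y| / |Y' \cup Y|} is available with
#'     \code{variant = "union"} (it exceeds 1 for overlapping masks and is
#'     kept only for comparison).
#'   \item \code{sensitivity}: \eqn{|Y' \cap Y| / |Y|}, the fraction of the
#'     reference recovered; undefined (NA, flagged) for an empty reference.
#'   \item \code{ppv}: \eqn{|Y' \cap Y| / |Y'|}, the fraction of the
#'     prediction that is correct; undefined for an empty prediction.
#' }
#' Wherever both are defined and nonzero, dice is their harmonic mean:
#' \code{dsc == 2 * sen * ppv / (sen + ppv)}.
#'
#' @param pred,ref Binary arrays of identical shape.
#' @param variant Denominator convention for \code{dsc}; default
#'   \code{"standard"}.
#' @return A scalar in \eqn{[0, 1]} (or NA when undefined), possibly with a
#'   \code{degenerate} attribute set to \code{TRUE}.
#' @examples
#' a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
#' b <- matrix(0, 4, 4); b[2:3, 1:2] <- 1
#' dsc(a, b)  # overlap 2 px: 2*2 / (4 + 4) = 0.5
#' @export
dsc <- function(pred, ref, variant = c("standard", "union")) {
  variant <- match.arg(variant)
  check_pair(pred, ref)
  inter <- sum(pred * ref)
  np <- sum(pred); nr <- sum(ref)
  if (np == 0 && nr == 0)
    return(structure(1, degenerate = TRUE))
  denom <- if (variant == "standard") np + nr else np + nr - inter
  2 * inter / denom
}

#' @rdname dsc
#' @export
sensitivity <- function(pred, ref) {
  check_pair(pred, ref)
  nr <- sum(ref)
  if (nr == 0) return(structure(NA_real_, degenerate = TRUE))
  sum(pred * ref) / nr
}

#' @rdname dsc
#' @export
ppv <- function(pred, ref) {
  check_pair(pred, ref)
  np <- sum(pred)
  if (np == 0) return(structure(NA_real_, degenerate = TRUE))
  sum(pred * ref) / np
}

check_pair <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)))
    stop("pred and ref shapes differ")
  as_binary(pred); as_binary(ref)
  invisible(NULL)
}

#' 50 percent annotator-consensus ground truth
#'
#' Combines the masks of \code{m} annotators into a single reference by
#' majority-at-half voting: a voxel is foreground when at least 50 percent
#' of annotators marked it, i.e. at least \code{ceiling(m / 2)} of them
#' (2 of 4 for the usual four-reader setting).
#'
#' @param annotator_masks Nonempty list of aligned binary arrays.
#' @return Binary array of the same shape.
#' @export
consensus_ground_truth <- function(annotator_masks) {
  m <- length(annotator_masks)
  if (m < 1L) stop("need at least one annotator mask")
  d <- dim(annotator_masks[[1]])
  for (a in annotator_masks)
    if (!identical(dim(a), d)) stop("annotator masks are not aligned")
  tally <- Reduce(`+`, lapply(annotator_masks, function(a) { as_binary(a); unclass(a) }))
  (tally >= ceiling(m / 2)) * 1
}

#' Summarise per-case evaluation results
#'
#' Aggregates a table of per-case metrics into mean +/- sd (sample sd,
#' n - 1; reported as 0 and flagged for a single case), optional
#' per-stratum means, and a dice histogram.
#'
#' @param results Data frame with columns \code{case_id}, \code{dsc},
#'   \code{sen}, \code{ppv} (e.g. one row per test nodule).
#' @param strata Optional vector of case labels (same length as rows) for
#'   stratified means, e.g. a nodule-characteristic grouping.
#' @param hist_breaks Bin edges for the dice histogram (default 0 to 1 in
#'   steps of 0.05).
#' @return A list with \code{overall} (data frame metric/mean/sd/n),
#'   \code{by_stratum} (data frame or NULL), and \code{dsc_hist}
#'   (data frame bin_lo/bin_hi/count).
#' @export
summarize_results <- function(results, strata = NULL,
                              hist_breaks = seq(0, 1, by = 0.05)) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  metrics <- intersect(c("dsc", "sen", "ppv"), names(results))
  overall <- do.call(rbind, lapply(metrics, function(m) {
    x <- results[[m]][!is.na(results[[m]])]
    data.frame(metric = m, mean = mean(x),
               sd = if (length(x) > 1L) sd(x) else 0,
               n = length(x))
  }))
  attr(overall, "single_case") <- nrow(results) == 1L
  by_stratum <- NULL
  if (!is.null(strata)) {
    stopifnot(length(strata) == nrow(results))
    sp <- split(seq_len(nrow(results)), strata)
    by_stratum <- do.call(rbind, lapply(names(sp), function(s) {
      g <- results[sp[[s]], , drop = FALSE]
      row <- data.frame(stratum = s, n = nrow(g))
      for (m in metrics) row[[m]] <- mean(g[[m]], na.rm = TRUE)
      row
    }))
  }
  h <- hist(pmin(pmax(results$dsc, 0), 1), breaks = hist_breaks, plot = FALSE)
  list(overall = overall, by_stratum = by_stratum,
       dsc_hist = data.frame(bin_lo = head(h$breaks, -1),
                             bin_hi = tail(h$breaks, -1),
                             count = h$counts))
}

#' @importFrom graphics hist
NULL
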