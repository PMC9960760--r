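#' Prepare a volume for segmentation
#'
#' Applies the two preprocessing steps in order: window normalisation to
#' [0, 1] and isotropic z-resampling. Returned alongside is the z-index map
#' so seed slices given on the original grid can be located on the
#' resampled one.
#'
#' @param volume A raw \code{\link{ct_volume}} with window metadata.
#' @return List \code{(volume, z_of_orig)} where \code{z_of_orig(k)} maps an
#'   original slice index to the resampled index.
#' @export
prepare_volume <- function(volume) {
  vn <- normalize_window(volume)
  zmm <- vn$spacing[1]; p <- vn$spacing[3]
  vr <- resample_z_isotropic(vn, order = "linear")
  nz_new <- dim(vr$voxels)[1]
  z_of_orig <- function(k) pmin(pmax(as.integer(round((k - 1) * zmm / p + 1)),
                                     1L), nz_new)
  list(volume = vr, z_of_orig = z_of_orig)
}

as_segmenter_list <- function(segmenters) {
  views <- c("axial", "sagittal", "coronal")
  if (!is.list(segmenters) || inherits(segmenters, c("dehanet", "threshold_segmenter")))
    segmenters <- setNames(rep(list(segmenters), 3L), views)
  missing <- setdiff(views, names(segmenters))
  if (length(missing))
    stop("no segmenter for view(s): ", paste(missing, collapse = ", "))
  segmenters
}

#' Two-stage volumetric nodule segmentation
#'
#' The full pipeline: window normalisation and isotropic resampling; stage 1
#' — bidirectional adaptive-ROI propagation along the axial axis from the
#' seed ROI; stage 2 — re-segmentation of every sagittal and coronal plane
#' the axial mask touches, with per-plane ROIs derived from that mask; and a
#' per-voxel thresholded vote over the three view masks. Any stage that
#' fails aborts with a stage-named error.
#'
#' @param volume A raw \code{\link{ct_volume}} (window metadata required).
#'   Pass \code{prepared = TRUE} if it is already normalised and resampled.
#' @param seed An axial \code{\link{roi_box}} (slice index on the input
#'   volume's grid) or \code{list(slice_index, mask)}.
#' @param segmenters One segmenter shared by all views, or a named list
#'   with elements \code{axial}, \code{sagittal}, \code{coronal}.
#' @param aroi An \code{\link{aroi_params}}.
#' @param tau Consensus vote threshold (1..3), e.g. from
#'   \code{\link{select_tau}}.
#' @param prepared Set TRUE when \code{volume} is already in [0, 1] at
#'   isotropic spacing (the seed slice index is then taken as-is).
#' @return List with the four \code{\link{nodule_mask}}s
#'   (\code{consensus}, \code{axial}, \code{sagittal}, \code{coronal}),
#'   the prepared \code{volume}, and a \code{manifest} (parameters, seed
#'   box, per-stage timings in seconds, the axial propagation trace, and
#'   package/R versions) suitable for JSON serialisation.
#' @export
segment_nodule <- function(volume, seed, segmenters, aroi = aroi_params(),
                           tau = 2L, prepared = FALSE) {
  segs <- as_segmenter_list(segmenters)
  timings <- c()
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  seed_slice_input <- seed$slice_index
  if (!prepared) {
    prep <- tic("preprocess", prepare_volume(volume))
    vol <- prep$volume
    seed$slice_index <- prep$z_of_orig(seed$slice_index)
  } else {
    vol <- volume
  }

  axial <- tic("axial_propagation",
               propagate_axial(segs$axial, vol, seed, aroi))
  sag <- tic("sagittal", {
    st <- extract_view(vol, axial, "sagittal", aroi)
    segment_view(segs$sagittal, st)
  })
  cor <- tic("coronal", {
    st <- extract_view(vol, axial, "coronal", aroi)
    segment_view(segs$coronal, st)
  })
  cons <- tic("consensus",
              vote(list(axial, sag, cor), consensus_params(3L, tau)))

  manifest <- list(
    parameters = list(rt = aroi$rt, tau = as.integer(tau),
                      threshold = segs$axial$threshold %||%
                        segs$axial$config$threshold),
    seed = c(list(slice = seed_slice_input,
                  slice_resampled = seed$slice_index),
             if (inherits(seed, "roi_box")) list(lo = seed$lo, hi = seed$hi)),
    volume_dim = dim(vol$voxels),
    spacing = vol$spacing,
    timings_s = as.list(timings),
    axial_trace = attr(axial, "trace"),
    axial_visits = as.list(attr(axial, "visits")),
    mask_voxels = list(axial = sum(axial), sagittal = sum(sag),
                       coronal = sum(cor), consensus = sum(cons)),
    versions = list(package = as.character(utils::packageVersion("noduleseg")),
                    r = R.version.string))
  list(consensus = cons, axial = axial, sagittal = sag, coronal = cor,
       volume = vol, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a seed ROI from a reference mask
#'
#' Emulates the radiologist's input for batch evaluation: takes the
#' nodule's largest-area axial slice and returns its bounding box dilated by
#' a fixed margin.
#'
#' @param gt3d Binary 3D mask (on the grid the pipeline will see).
#' @param margin Pixels added on every side (default 5).
#' @return An axial \code{\link{roi_box}}.
#' @export
seed_from_mask <- function(gt3d, margin = 5L) {
  areas <- apply(gt3d, 1, sum)
  if (max(areas) == 0) stop("mask is empty")
  z <- which.max(areas)
  bb <- mask_bbox(gt3d[z, , ])
  d <- dim(gt3d)
  roi_box("axial", z,
          lo = c(max(1L, bb$r0 - margin), max(1L, bb$c0 - margin)),
          hi = c(min(d[2], bb$r1 + margin), min(d[3], bb$c1 + margin)))
}

#' Build a training set from phantom cases
#'
#' Prepares each case (normalise + resample), resamples its 50-percent
#' consensus reference to the same isotropic grid (nearest-neighbour), and
#' collects per-slice training samples across cases.
#'
#' @param cases List of phantom cases (see \code{\link{generate_dataset}}).
#' @param n_flank,margin_range Passed to \code{\link{sample_training_set}}.
#' @param reference \code{"consensus"} (default; the 50-percent annotator
#'   consensus, as when training against reader annotations) or
#'   \code{"exact"} (the generator's true mask).
#' @return List of training samples.
#' @export
training_samples_from_cases <- function(cases, n_flank = 2L,
                                        margin_range = c(1L, 10L),
                                        reference = c("consensus", "exact")) {
  reference <- match.arg(reference)
  out <- list()
  for (case in cases) {
    prep <- prepare_volume(case$volume)
    ref <- if (reference == "consensus") case$gt_consensus else case$gt
    gt_res <- resample_z_isotropic(
      ct_volume(ref, case$volume$spacing), order = "nearest")$voxels
    out <- c(out, sample_training_set(prep$volume, gt_res, n_flank = n_flank,
                                      margin_range = margin_range))
  }
  out
}

#' Evaluate the pipeline on phantom cases
#'
#' Runs \code{\link{segment_nodule}} on every case — seeding each from its
#' reference mask via \code{\link{seed_from_mask}} — and scores the
#' consensus and per-view masks against the case reference (the 50-percent
#' annotator consensus by default) resampled to the prediction grid. A case
#' whose pipeline fails (e.g. stage 1 found nothing) scores 0.
#'
#' @param cases List of phantom cases.
#' @param segmenters As in \code{\link{segment_nodule}}.
#' @param aroi,tau As in \code{\link{segment_nodule}}.
#' @param reference \code{"consensus"} or \code{"exact"}.
#' @param seed_margin Margin of the emulated user seed box (default 5 px).
#' @return Data frame with one row per case: \code{case_id}, \code{dsc},
#'   \code{sen}, \code{ppv} (consensus mask) and \code{dsc_axial},
#'   \code{dsc_sagittal}, \code{dsc_coronal}.
#' @export
evaluate_cases <- function(cases, segmenters, aroi = aroi_params(),
                           tau = 2L, reference = c("consensus", "exact"),
                           seed_margin = 5L) {
  reference <- match.arg(reference)
  rows <- lapply(cases, function(case) {
    ref0 <- if (reference == "consensus") case$gt_consensus else case$gt
    gt_res <- resample_z_isotropic(
      ct_volume(ref0, case$volume$spacing), order = "nearest")$voxels
    res <- tryCatch({
      # the emulated user seed lives on the original (anisotropic) grid;
      # segment_nodule maps its slice index onto the resampled grid
      seed <- seed_from_mask(ref0, margin = seed_margin)
      segment_nodule(case$volume, seed, segmenters, aroi = aroi, tau = tau)
    }, error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(case_id = case$id, dsc = 0, sen = 0, ppv = NA,
                        dsc_axial = 0, dsc_sagittal = 0, dsc_coronal = 0))
    }
    data.frame(case_id = case$id,
               dsc = as.numeric(dsc(res$consensus, gt_res)),
               sen = as.numeric(sensitivity(res$consensus, gt_res)),
               ppv = as.numeric(ppv(res$consensus, gt_res)),
               dsc_axial = as.numeric(dsc(res$axial, gt_res)),
               dsc_sagittal = as.numeric(dsc(res$sagittal, gt_res)),
               dsc_coronal = as.numeric(dsc(res$coronal, gt_res)))
  })
  do.call(rbind, rows)
}

#' Collect per-case mask stacks for vote-threshold selection
#'
#' Runs the three-view pipeline on validation cases and packages the
#' per-view masks with the reference, in the shape
#' \code{\link{select_tau}} expects.
#'
#' @inheritParams evaluate_cases
#' @return List of \code{list(masks = list(axial, sagittal, coronal), gt)}.
#' @export
validation_mask_stacks <- function(cases, segmenters, aroi = aroi_params(),
                                   reference = c("consensus", "exact"),
                                   seed_margin = 5L) {
  reference <- match.arg(reference)
  lapply(cases, function(case) {
    ref0 <- if (reference == "consensus") case$gt_consensus else case$gt
    gt_res <- resample_z_isotropic(
      ct_volume(ref0, case$volume$spacing), order = "nearest")$voxels
    seed <- seed_from_mask(ref0, margin = seed_margin)
    res <- segment_nodule(case$volume, seed, segmenters, aroi = aroi, tau = 1L)
    list(masks = list(res$axial, res$sagittal, res$coronal), gt = gt_res)
  })
}
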