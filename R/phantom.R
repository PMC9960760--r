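#' Synthetic CT phantom specification
#'
#' Parameters of a CT-like test scene: an anisotropic voxel grid (slice
#' spacing coarser than pixel spacing, as in clinical thoracic CT), a
#' bright, optionally lobulated and rotated ellipsoidal nodule, tubular
#' vessel-like distractors attached to the nodule surface, a smooth
#' low-frequency background texture, additive Gaussian noise, and a set of
#' simulated annotators whose masks jitter the true boundary. Intensities
#' are on an HU-like scale, and the window metadata is chosen so that after
#' \code{\link{normalize_window}} the background sits near 0.3 and the
#' nodule near 0.8.
#'
#' @param volume_shape Voxels (nz, ny, nx); default \code{c(64, 64, 64)}.
#' @param spacing (z_mm, y_mm, x_mm); default \code{c(2.0, 0.7, 0.7)} so
#'   z-resampling has real work to do.
#' @param center_mm Nodule centre in mm from the volume corner; default the
#'   volume centre.
#' @param semi_axes_mm Ellipsoid semi-axes (z, y, x) in mm; default 5 mm.
#' @param lobulation Relative boundary modulation amplitude in [0, 0.3);
#'   0 gives a smooth ellipsoid.
#' @param rotation In-plane rotation of the ellipsoid, radians.
#' @param background_hu,nodule_hu,vessel_hu Intensities of the three tissue
#'   classes (defaults -600 / -100 / -300).
#' @param n_vessels Number of attached tubular distractors (default 2).
#' @param vessel_radius_mm Tube radius (default 1 mm).
#' @param texture_amp Amplitude of the smooth background texture, HU
#'   (default 40).
#' @param noise_sd Additive Gaussian noise, HU (default 20).
#' @param n_annotators Simulated readers (default 4, as in four-radiologist
#'   annotation protocols).
#' @param annotator_jitter Probability that an annotator flips a voxel in
#'   the one-voxel boundary band of the true mask (default 0.15); 0 makes
#'   every annotator reproduce the truth.
#' @param seed Integer; fixes all randomness of \code{\link{generate_phantom}}.
#' @return A \code{phantom_spec} object.
#' @export
phantom_spec <- function(volume_shape = c(64L, 64L, 64L),
                         spacing = c(2.0, 0.7, 0.7),
                         center_mm = NULL,
                         semi_axes_mm = c(5, 5, 5),
                         lobulation = 0.1,
                         rotation = 0,
                         background_hu = -600, nodule_hu = -100,
                         vessel_hu = -300,
                         n_vessels = 2L, vessel_radius_mm = 1.0,
                         texture_amp = 40, noise_sd = 20,
                         n_annotators = 4L, annotator_jitter = 0.15,
                         seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  spacing <- as.numeric(spacing)
  if (any(semi_axes_mm <= 0)) stop("semi-axes must be positive")
  if (lobulation < 0 || lobulation >= 0.3) stop("lobulation must be in [0, 0.3)")
  extent_mm <- volume_shape * spacing  # (z, y, x)
  if (is.null(center_mm)) center_mm <- extent_mm / 2
  reach <- max(semi_axes_mm) * (1 + lobulation)
  if (any(center_mm - reach < 0) || any(center_mm + reach > extent_mm))
    stop("nodule does not fit inside the volume")
  structure(list(volume_shape = volume_shape, spacing = spacing,
                 center_mm = as.numeric(center_mm),
                 semi_axes_mm = as.numeric(semi_axes_mm),
                 lobulation = lobulation, rotation = rotation,
                 background_hu = background_hu, nodule_hu = nodule_hu,
                 vessel_hu = vessel_hu, n_vessels = as.integer(n_vessels),
                 vessel_radius_mm = vessel_radius_mm,
                 texture_amp = texture_amp, noise_sd = noise_sd,
                 n_annotators = as.integer(n_annotators),
                 annotator_jitter = annotator_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

shift_arr <- function(m, axis, by) {
  d <- dim(m)
  out <- array(0, d)
  src <- lapply(d, seq_len)
  dst <- src
  n <- d[axis]
  if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
  else if (by < 0) { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

boundary_band <- function(gt) {
  nb <- gt
  for (ax in 1:3) for (by in c(-1L, 1L))
    nb <- pmax(nb, shift_arr(gt, ax, by))
  inner <- gt
  for (ax in 1:3) for (by in c(-1L, 1L))
    inner <- pmin(inner, shift_arr(gt, ax, by))
  nb - inner  # dilation minus erosion: the one-voxel boundary shell
}

#' Generate a phantom scene
#'
#' Renders the scene described by a \code{\link{phantom_spec}}. All
#' randomness (texture phases, vessel placement, noise, annotator jitter)
#' derives from \code{spec$seed}, so the same spec always yields
#' bit-identical output; the caller's RNG stream is left untouched.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A list with \code{volume} (a \code{\link{ct_volume}} with window
#'   metadata), \code{gt} (exact binary nodule mask), \code{annotators}
#'   (list of jittered binary masks), \code{gt_consensus} (their
#'   50-percent consensus), and \code{meta} (nodule bounding box, z extent,
#'   centre voxel, the spec).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$volume_shape
  sp <- spec$spacing
  # voxel-centre coordinates in mm, relative to the nodule centre
  zc <- (seq_len(d[1]) - 0.5) * sp[1] - spec$center_mm[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2] - spec$center_mm[2]
  xc <- (seq_len(d[3]) - 0.5) * sp[3] - spec$center_mm[3]
  Z <- array(zc, d)
  Y <- array(rep(yc, each = d[1]), d)
  X <- array(rep(xc, each = d[1] * d[2]), d)

  ca <- cos(spec$rotation); sa <- sin(spec$rotation)
  Xr <- ca * X + sa * Y
  Yr <- -sa * X + ca * Y
  ax <- spec$semi_axes_mm  # (z, y, x)
  rho <- sqrt((Z / ax[1])^2 + (Yr / ax[2])^2 + (Xr / ax[3])^2)

  ph <- runif(2, 0, 2 * pi)
  theta <- atan2(Yr, Xr)
  phi <- atan2(Z, sqrt(Xr^2 + Yr^2))
  rmod <- 1 + spec$lobulation * sin(3 * theta + ph[1]) * cos(2 * phi + ph[2])
  gt <- (rho <= rmod) * 1

  vox <- array(spec$background_hu, d)
  if (spec$texture_amp > 0) {
    tp <- runif(3, 0, 2 * pi)
    wl <- runif(3, 15, 40)  # mm wavelengths
    vox <- vox + spec$texture_amp / 3 *
      (sin(2 * pi * Z / wl[1] + tp[1]) + sin(2 * pi * Yr / wl[2] + tp[2]) +
         sin(2 * pi * Xr / wl[3] + tp[3]))
  }
  if (spec$n_vessels > 0) {
    P <- cbind(as.vector(Z), as.vector(Y), as.vector(X))
    for (v in seq_len(spec$n_vessels)) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      # anchor on the ellipsoid surface along dir, tube extends outward
      tsurf <- 1 / sqrt(sum((dir / ax)^2))
      a <- dir * tsurf
      len <- runif(1, 10, 25)
      tv <- (P - matrix(a, nrow(P), 3, byrow = TRUE)) %*% dir
      tv <- pmin(pmax(tv, 0), len)
      Q <- matrix(a, nrow(P), 3, byrow = TRUE) + tv %*% t(dir)
      dist <- sqrt(rowSums((P - Q)^2))
      tube <- array(dist <= spec$vessel_radius_mm, d) & gt == 0
      vox[tube] <- pmax(vox[tube], spec$vessel_hu)
    }
  }
  vox[gt == 1] <- spec$nodule_hu
  if (spec$noise_sd > 0)
    vox <- vox + array(rnorm(prod(d), 0, spec$noise_sd), d)

  # window: background -> 0.3, nodule -> 0.8 after normalisation
  ww <- (spec$nodule_hu - spec$background_hu) / 0.5
  wmin <- spec$background_hu - 0.3 * ww
  window <- window_spec(wc = wmin + ww / 2, ww = ww)

  annotators <- lapply(seq_len(spec$n_annotators), function(a) {
    if (spec$annotator_jitter <= 0) return(gt)
    band <- boundary_band(gt)
    flips <- band == 1 & array(runif(prod(d)) < spec$annotator_jitter, d)
    m <- gt
    m[flips] <- 1 - m[flips]
    m
  })

  idx <- which(gt == 1, arr.ind = TRUE)
  meta <- list(bbox = apply(idx, 2, range),
               z_extent = c(min(idx[, 1]), max(idx[, 1])),
               center_voxel = round(spec$center_mm / sp + 0.5),
               n_voxels = nrow(idx),
               spec = spec)
  list(volume = ct_volume(vox, sp, window), gt = gt,
       annotators = annotators,
       gt_consensus = consensus_ground_truth(annotators),
       meta = meta)
}

#' Generate a reproducible phantom dataset with splits
#'
#' Draws \code{n_cases} phantom specs with inter-nodule variation (size,
#' lobulation, rotation, contrast, vessel count, noise), renders each, and
#' partitions them into train / validation / test sets. Split sizes follow
#' the 40/5/55 percent convention: \code{floor} for train and validation,
#' remainder to test (20 cases give 8 / 1 / 11).
#'
#' @param n_cases At least 3.
#' @param seed Integer; fixes the spec draws, the per-case render seeds and
#'   the split assignment.
#' @param ratios Length-3 proportions for train/validation/test (default
#'   \code{c(0.40, 0.05, 0.55)}).
#' @param base_spec Template \code{\link{phantom_spec}}; per-case draws
#'   override nodule shape/contrast fields.
#' @return List with \code{train}, \code{val}, \code{test}: each a list of
#'   cases, a case being the \code{\link{generate_phantom}} output plus an
#'   \code{id}.
#' @export
generate_dataset <- function(n_cases, seed = 1L,
                             ratios = c(0.40, 0.05, 0.55),
                             base_spec = phantom_spec()) {
  if (n_cases < 3L) stop("need at least 3 cases")
  stopifnot(abs(sum(ratios) - 1) < 1e-9)
  cases <- withr::with_seed(seed, {
    case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
    lapply(seq_len(n_cases), function(i) {
      extent <- base_spec$volume_shape * base_spec$spacing
      spec <- phantom_spec(
        volume_shape = base_spec$volume_shape,
        spacing = base_spec$spacing,
        center_mm = extent / 2 + c(runif(1, -4, 4), runif(1, -4, 4),
                                   runif(1, -4, 4)),
        semi_axes_mm = runif(3, 3.0, 6.5),
        lobulation = runif(1, 0, 0.15),
        rotation = runif(1, 0, pi),
        background_hu = base_spec$background_hu,
        nodule_hu = base_spec$nodule_hu + runif(1, -50, 50),
        vessel_hu = base_spec$vessel_hu,
        n_vessels = sample(0:3, 1),
        vessel_radius_mm = base_spec$vessel_radius_mm,
        texture_amp = base_spec$texture_amp,
        noise_sd = base_spec$noise_sd,
        n_annotators = base_spec$n_annotators,
        annotator_jitter = base_spec$annotator_jitter,
        seed = case_seeds[i])
      ph <- generate_phantom(spec)
      ph$id <- sprintf("case_%03d", i)
      ph
    })
  })
  n_tr <- floor(ratios[1] * n_cases)
  n_va <- floor(ratios[2] * n_cases)
  ord <- withr::with_seed(seed + 1L, sample.int(n_cases))
  list(train = cases[ord[seq_len(n_tr)]],
       val = cases[ord[n_tr + seq_len(n_va)]],
       test = cases[ord[(n_tr + n_va + 1L):n_cases]])
}
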