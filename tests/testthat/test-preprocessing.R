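make_vol <- function(vals, dims = c(2, 2, 2), spacing = c(1, 1, 1),
                     wc = NULL, ww = NULL) {
  win <- if (!is.null(wc)) window_spec(wc, ww) else NULL
  ct_volume(array(vals, dims), spacing, win)
}

test_that("window normalisation maps the window linearly onto [0, 1] and clips", {
  v <- make_vol(c(-1, 1, 0, -5, 5, 0.5, -0.5, 0), wc = 0, ww = 2)
  out <- normalize_window(v)$voxels
  expect_equal(out[1], 0)    # intensity at the window floor
  expect_equal(out[2], 1)    # at the ceiling
  expect_equal(out[3], 0.5)  # at the centre
  expect_equal(out[4], 0)    # clipped below
  expect_equal(out[5], 1)    # clipped above

  # soft-tissue window: WC 40, WW 400 -> floor -160; (40 - (-160)) / 400
  v2 <- make_vol(rep(40, 8), wc = 40, ww = 400)
  expect_equal(normalize_window(v2)$voxels[1], 0.5)
})

test_that("window normalisation is affine inside the window and monotone overall", {
  for (wc in c(-600, 0, 40)) for (ww in c(2, 400, 1500)) {
    wmin <- wc - ww / 2; wmax <- wc + ww / 2
    I <- seq(wmin - ww, wmax + ww, length.out = 41)
    out <- normalize_window(make_vol(rep(I, length.out = 48), c(48, 1, 1),
                                     wc = wc, ww = ww))$voxels[1:41]
    inside <- I >= wmin & I <= wmax
    expect_equal(out[inside], (I[inside] - wmin) / ww, tolerance = 1e-12)
    expect_true(all(diff(out) >= -1e-12))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("windowing errors name the missing metadata and reject bad widths", {
  expect_error(normalize_window(make_vol(0)), "WindowCenter/WindowWidth")
  expect_error(window_spec(0, 0), "width")
  expect_error(window_spec(0, -5), "width")
})

test_that("z resampling reaches pixel spacing with the expected slice count", {
  v <- ct_volume(array(rnorm(10 * 4 * 4), c(10, 4, 4)), c(2.0, 0.5, 0.5))
  out <- resample_z_isotropic(v)
  expect_identical(dim(out$voxels), c(40L, 4L, 4L))
  expect_equal(out$spacing, c(0.5, 0.5, 0.5))

  iso <- ct_volume(array(1:8, c(2, 2, 2)), c(0.7, 0.7, 0.7))
  expect_identical(resample_z_isotropic(iso), iso)

  const <- ct_volume(array(3.7, c(5, 3, 3)), c(2.1, 0.7, 0.7))
  expect_equal(unique(as.vector(resample_z_isotropic(const)$voxels)), 3.7)
})

test_that("integer-ratio upsampling reproduces every original slice", {
  v <- ct_volume(array(rnorm(6 * 5 * 5), c(6, 5, 5)), c(2.1, 0.7, 0.7))
  out <- resample_z_isotropic(v)
  expect_identical(dim(out$voxels)[1], 18L)
  for (i in 1:6)
    expect_equal(out$voxels[3 * (i - 1) + 1, , ], v$voxels[i, , ],
                 tolerance = 1e-12)
})

test_that("finer-than-pixel z spacing is left alone with a warning", {
  v <- ct_volume(array(0, c(4, 4, 4)), c(0.5, 0.7, 0.7))
  expect_warning(out <- resample_z_isotropic(v), "unchanged")
  expect_identical(out$voxels, v$voxels)
})

test_that("mask resampling stays binary under nearest-neighbour", {
  m <- array(0, c(5, 4, 4)); m[2:3, 2:3, 2:3] <- 1
  out <- resample_z_isotropic(ct_volume(m, c(2.0, 0.7, 0.7)), "nearest")
  expect_true(all(out$voxels %in% c(0, 1)))
  expect_gt(sum(out$voxels), sum(m))
})

test_that("training ROI is the ground-truth box dilated per side within range", {
  # deterministic margins: degenerate draw range
  gt <- matrix(0, 32, 32); gt[11, 11] <- 1
  roi <- make_training_roi(gt, margin_range = c(2, 2))
  idx <- which(roi == 1, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(9, 13))
  expect_equal(range(idx[, 2]), c(9, 13))

  # property: over random masks the ROI strictly contains the gt bbox and
  # margins respect the configured range
  set.seed(41)
  for (rep in 1:30) {
    gt <- random_mask2d(c(30, 30))
    roi <- make_training_roi(gt, margin_range = c(1, 10))
    bb <- which(gt == 1, arr.ind = TRUE)
    rb <- which(roi == 1, arr.ind = TRUE)
    # lower bound: at least one pixel of margin unless clipped at the edge
    expect_true(min(rb[, 1]) == 1 || min(rb[, 1]) <= min(bb[, 1]) - 1)
    expect_true(max(rb[, 1]) == 30 || max(rb[, 1]) >= max(bb[, 1]) + 1)
    expect_true(all(roi[gt == 1] == 1))
    # margin per side at most 10 where no clipping occurred
    expect_gte(min(rb[, 1]), min(bb[, 1]) - 10)
    expect_lte(max(rb[, 1]), max(bb[, 1]) + 10)
    expect_gte(min(rb[, 2]), min(bb[, 2]) - 10)
    expect_lte(max(rb[, 2]), max(bb[, 2]) + 10)
  }
})

test_that("training ROI clips at image bounds and rejects empty masks", {
  gt <- matrix(0, 12, 12); gt[1, 1] <- 1
  roi <- make_training_roi(gt, margin_range = c(10, 10))
  idx <- which(roi == 1, arr.ind = TRUE)
  expect_equal(min(idx[, 1]), 1)
  expect_equal(max(idx[, 1]), 11)
  expect_error(make_training_roi(matrix(0, 5, 5)), "empty")
})

test_that("per-slice training set covers the nodule plus flanking slices", {
  d <- c(16, 20, 20)
  gt <- array(0, d); gt[6:10, 8:12, 8:12] <- 1
  vol <- ct_volume(array(0.3, d) + 0.5 * gt, c(0.7, 0.7, 0.7),
                   window_spec(0.5, 1))
  vol$voxels <- pmin(vol$voxels, 1)
  samples <- sample_training_set(vol, gt, n_flank = 2)
  expect_length(samples, 9)  # 5 nodular + 2 per side
  expect_equal(vapply(samples, function(s) s$z, numeric(1)), 4:12)
  nod <- vapply(samples, function(s) s$is_nodular, logical(1))
  expect_equal(sum(nod), 5)
  for (s in samples) {
    expect_identical(dim(s$roi_mask), dim(s$image))
    if (!s$is_nodular) expect_equal(sum(s$target), 0)
    else expect_true(all(s$roi_mask[s$target == 1] == 1))
  }

  # nodule touching the first slice: truncated flank
  gt2 <- array(0, d); gt2[1:3, 8:12, 8:12] <- 1
  s2 <- sample_training_set(vol, gt2, n_flank = 2)
  expect_equal(vapply(s2, function(s) s$z, numeric(1)), 1:5)
})
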