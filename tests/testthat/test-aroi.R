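test_that("ROI derivation re-centres and rescales the box by the margin ratio", {
  seg <- matrix(0, 48, 48); seg[21:30, 21:30] <- 1  # 10x10 square
  roi <- roi_from_segmentation(seg, aroi_params(0.2))
  idx <- which(roi == 1, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(19, 32))  # ceiling(0.2 * 10) = 2 per side
  expect_equal(range(idx[, 2]), c(19, 32))
  expect_identical(roi, bf_roi(seg, 0.2))
})

test_that("an empty segmentation yields the blank termination ROI", {
  out <- roi_from_segmentation(matrix(0, 10, 10), aroi_params(0.3))
  expect_equal(sum(out), 0)
  expect_identical(dim(out), c(10L, 10L))
})

test_that("ROI derivation matches the brute-force margin oracle over random masks", {
  set.seed(23)
  for (rep in 1:500) {
    seg <- random_mask2d(c(20, 20), p = runif(1, 0.03, 0.4))
    rt <- runif(1, 0.02, 0.98)
    expect_identical(roi_from_segmentation(seg, aroi_params(rt)),
                     bf_roi(seg, rt))
  }
})

test_that("larger margin ratios never shrink the ROI; boxes clip at edges", {
  set.seed(29)
  for (rep in 1:40) {
    seg <- random_mask2d(c(25, 25))
    prev <- NULL
    for (rt in c(0.1, 0.3, 0.5, 0.8)) {
      roi <- roi_from_segmentation(seg, aroi_params(rt))
      expect_true(all(roi[seg == 1] == 1))  # always contains the mask
      if (!is.null(prev)) expect_true(all(prev <= roi))
      prev <- roi
    }
  }
  edge <- matrix(0, 12, 12); edge[1:3, 10:12] <- 1
  roi <- roi_from_segmentation(edge, aroi_params(0.9))
  expect_true(all(roi[edge == 1] == 1))
  expect_identical(roi, bf_roi(edge, 0.9))
  expect_error(aroi_params(0), "rt")
  expect_error(aroi_params(1), "rt")
})

test_that("axial propagation with the oracle recovers the phantom on every slice", {
  ph <- generate_phantom(clean_phantom_spec())
  vol <- normalize_window(ph$volume)  # isotropic already: no resampling
  ze <- ph$meta$z_extent
  zseed <- round(mean(ze))
  seed <- seed_from_mask(ph$gt, margin = 4)
  res <- propagate_axial(threshold_segmenter(0.55), vol, seed, aroi_params(0.3))
  expect_equal(as.numeric(dsc(unclass(res) * 1, ph$gt)), 1)
  for (z in ze[1]:ze[2])
    expect_equal(res[z, , ], ph$gt[z, , ], info = paste("slice", z))
  # visits: every nodular slice from the seed outwards, plus the blank stop
  visits <- attr(res, "visits")
  expect_equal(as.integer(visits["up"]), (ze[2] - seed$slice_index + 1) + 1)
  expect_equal(as.integer(visits["down"]), (seed$slice_index - ze[1] + 1) + 1)
  nz <- dim(vol$voxels)[1]
  expect_lte(as.integer(visits["up"]), nz + 1)
  expect_lte(as.integer(visits["down"]), nz + 1)
})

test_that("propagation terminates immediately when the seed slice is empty", {
  vol <- ct_volume(array(0.2, c(8, 16, 16)), c(1, 1, 1))
  seed <- roi_box("axial", 4, lo = c(5, 5), hi = c(12, 12))
  res <- propagate_axial(threshold_segmenter(0.5), vol, seed)
  expect_equal(sum(res), 0)
  visits <- attr(res, "visits")
  expect_equal(as.integer(visits["up"]), 1L)
  expect_equal(as.integer(visits["down"]), 1L)
})

test_that("propagation stops at the volume boundary when the nodule touches it", {
  d <- c(6, 16, 16)
  gt <- array(0, d); gt[3:6, 6:10, 6:10] <- 1  # extends to the last slice
  vol <- ct_volume(array(0.3, d) + 0.4 * gt, c(1, 1, 1))
  seed <- roi_box("axial", 4, lo = c(4, 4), hi = c(12, 12))
  res <- propagate_axial(threshold_segmenter(0.5), vol, seed)
  expect_equal(unclass(res) * 1, gt, ignore_attr = TRUE)
  expect_lte(as.integer(attr(res, "visits")["up"]), d[1] + 1)
})

test_that("propagation validates its seed", {
  vol <- ct_volume(array(0.2, c(8, 16, 16)), c(1, 1, 1))
  expect_error(propagate_axial(threshold_segmenter(), vol,
                               roi_box("axial", 99, c(1, 1), c(2, 2))),
               "outside")
  expect_error(propagate_axial(threshold_segmenter(), vol,
                               list(slice_index = 4, mask = matrix(0, 16, 16))),
               "empty")
})
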