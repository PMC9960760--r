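test_that("dice, sensitivity and PPV match brute-force pixel counting", {
  set.seed(7)
  for (rep in 1:40) {
    a <- random_mask2d(c(15, 15), p = runif(1, 0.05, 0.5))
    b <- random_mask2d(c(15, 15), p = runif(1, 0.05, 0.5))
    expect_equal(as.numeric(dsc(a, b)), bf_dsc(a, b), tolerance = 1e-12)
    expect_equal(as.numeric(sensitivity(a, b)), bf_sen(a, b), tolerance = 1e-12)
    expect_equal(as.numeric(ppv(a, b)), bf_ppv(a, b), tolerance = 1e-12)
  }
})

test_that("worked examples: overlap fractions come out exactly", {
  a <- matrix(0, 6, 6); a[1:2, 1:2] <- 1        # 4 px
  b <- matrix(0, 6, 6); b[2:3, 1:2] <- 1        # 4 px, overlap 2
  expect_equal(as.numeric(dsc(a, b)), 0.5)
  expect_equal(as.numeric(dsc(a, a)), 1)
  disj <- matrix(0, 6, 6); disj[5:6, 5:6] <- 1
  expect_equal(as.numeric(dsc(a, disj)), 0)
  expect_equal(as.numeric(sensitivity(a, b)), 0.5)   # 2 of ref's 4
  big <- matrix(0, 6, 6); big[1:4, 1:2] <- 1         # 8 px, contains all of a
  expect_equal(as.numeric(ppv(big, a)), 0.5)         # 4 of pred's 8 are in a
  expect_equal(as.numeric(sensitivity(big, a)), 1)   # pred covers ref
})

test_that("metric identities hold: symmetry, SEN/PPV duality, harmonic mean", {
  set.seed(11)
  for (rep in 1:25) {
    a <- random_mask2d(); b <- random_mask2d()
    expect_equal(as.numeric(dsc(a, b)), as.numeric(dsc(b, a)), tolerance = 1e-15)
    expect_equal(as.numeric(sensitivity(a, b)), as.numeric(ppv(b, a)),
                 tolerance = 1e-15)
    s <- as.numeric(sensitivity(a, b)); p <- as.numeric(ppv(a, b))
    if (s > 0 && p > 0)
      expect_equal(as.numeric(dsc(a, b)), 2 * s * p / (s + p),
                   tolerance = 1e-12)
  }
})

test_that("degenerate masks are flagged, not silently scored", {
  e <- matrix(0, 4, 4)
  d0 <- dsc(e, e)
  expect_equal(as.numeric(d0), 1)
  expect_true(attr(d0, "degenerate"))
  expect_true(is.na(sensitivity(matrix(1, 4, 4), e)))
  expect_true(is.na(ppv(e, matrix(1, 4, 4))))
  full <- matrix(1, 4, 4)
  expect_error(dsc(full, matrix(1, 2, 8)), "shape")
  expect_error(dsc(full * 2, full), "binary")
})

test_that("union-denominator dice variant scores 2 for identical masks (why it is not the default)", {
  a <- matrix(0, 6, 6); a[1:2, 1:2] <- 1
  b <- matrix(0, 6, 6); b[2:3, 1:2] <- 1
  expect_equal(as.numeric(dsc(a, a, variant = "union")), 2)  # 2|A|/|A|
  # overlap 2, union 6: 2*2/6 differs from the standard 0.5
  expect_equal(as.numeric(dsc(a, b, variant = "union")), 2 / 3)
  # the two variants agree only when the masks are disjoint
  d <- matrix(0, 6, 6); d[5:6, 5:6] <- 1
  expect_equal(as.numeric(dsc(a, d, variant = "union")),
               as.numeric(dsc(a, d)))
})

test_that("50 percent annotator consensus equals the ceiling(m/2) vote table", {
  # all 2^4 per-voxel patterns for four annotators in one 16-voxel image
  pat <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  masks <- lapply(1:4, function(j) matrix(pat[, j], 4, 4))
  got <- consensus_ground_truth(masks)
  expect_equal(as.vector(got), as.numeric(rowSums(pat) >= 2))
  # equivalently: a K = 4, tau = 2 vote
  expect_equal(as.vector(got),
               as.vector(vote(masks, consensus_params(4, 2))))
  # a single annotator is their own consensus
  expect_equal(consensus_ground_truth(masks[1]), masks[[1]])
})

test_that("result summaries aggregate mean, sd, strata and histogram correctly", {
  res <- data.frame(case_id = c("a", "b", "c", "d"),
                    dsc = c(0.8, 0.9, 0.6, 0.7),
                    sen = c(0.9, 0.95, 0.7, 0.8),
                    ppv = c(0.85, 0.9, 0.65, 0.75))
  s <- summarize_results(res, strata = c("small", "small", "large", "large"))
  ov <- s$overall
  expect_equal(ov$mean[ov$metric == "dsc"], mean(res$dsc))
  expect_equal(ov$sd[ov$metric == "dsc"], sd(res$dsc))
  # stratified means equal a brute-force group-by
  for (g in c("small", "large")) {
    rows <- res[c("small", "small", "large", "large") == g, ]
    expect_equal(s$by_stratum$dsc[s$by_stratum$stratum == g], mean(rows$dsc))
  }
  expect_equal(sum(s$dsc_hist$count), 4)

  one <- summarize_results(res[1, ])
  expect_equal(one$overall$sd, rep(0, 3))
})
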