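tiny_cfg <- function(...) dehanet_config(input_size = c(32, 32),
                                         width_scale = 0.125, ...)

test_that("network construction follows the level arithmetic exactly", {
  cfg <- dehanet_config(input_size = c(64, 64), width_scale = 1)
  expect_equal(cfg$filters, c(32, 128, 288, 512))  # 32 * n^2
  cfg2 <- dehanet_config(filter_rule = "doubling")
  expect_equal(cfg2$filters, c(32, 64, 128, 256))
  expect_error(dehanet_config(input_size = c(60, 64)), "divisible")

  # parameter count against an independent layer-by-layer tally
  cfg3 <- tiny_cfg()
  f <- cfg3$filters
  expected <- 0
  for (enc in 1:2) for (n in 1:4) {
    cin <- if (n == 1) 1 else f[n - 1]
    expected <- expected + 9 * cin * f[n] + f[n] + 2 * f[n]  # conv w+b, bn g+b
  }
  for (n in 4:1) {
    cin <- 2 * f[n] + if (n == 4) 2 * f[4] else f[n + 1]
    expected <- expected + 9 * cin * f[n] + f[n] + 2 * f[n]
  }
  expected <- expected + f[1] * 1 + 1  # 1x1 output conv
  net <- build_dehanet(cfg3)
  expect_equal(dehanet_n_params(net), expected)
})

test_that("an untrained network already satisfies the output contract", {
  set.seed(51)
  net <- build_dehanet(tiny_cfg())
  img <- matrix(runif(32 * 32), 32, 32)
  roi <- matrix(0, 32, 32); roi[10:20, 12:22] <- 1
  expect_warning(sg <- segment_slice(net, img, roi), "untrained")
  expect_identical(dim(sg$prob), c(32L, 32L))
  expect_true(all(is.finite(sg$prob)))
  expect_true(all(sg$prob >= 0 & sg$prob <= 1))
  expect_true(all(sg$mask %in% c(0, 1)))

  # all-zero ROI: probabilities still finite, hard attention blanks the mask
  sg0 <- suppressWarnings(segment_slice(net, img, matrix(0, 32, 32)))
  expect_true(all(is.finite(sg0$prob)))
  expect_equal(sum(sg0$mask), 0)

  # whole-slice ROI leaves the thresholded map unconstrained
  sg1 <- suppressWarnings(segment_slice(net, img, matrix(1, 32, 32)))
  expect_equal(sg1$mask, (sg1$prob >= 0.5) * 1)

  # inference is deterministic
  sg2 <- suppressWarnings(segment_slice(net, img, roi))
  expect_identical(sg$prob, sg2$prob)
})

test_that("dice loss matches the counting oracle and complements the dice metric", {
  set.seed(53)
  t1 <- random_mask2d(c(16, 16)); t2 <- random_mask2d(c(16, 16))
  # perfect and inverted predictions
  expect_lt(dice_loss(t1, t1), 1e-6)
  expect_gt(dice_loss(1 - t1, t1), 1 - 1e-3)

  # batch of two equals the mean of per-sample brute-force losses
  p <- array(runif(16 * 16 * 2), c(16, 16, 2))
  t <- array(c(t1, t2), c(16, 16, 2))
  bf_soft <- function(p, t) {
    num <- 0; dp <- 0; dt <- 0
    for (i in seq_along(p)) { num <- num + p[i] * t[i]; dp <- dp + p[i]; dt <- dt + t[i] }
    1 - (2 * num + 1e-6) / (dp + dt + 1e-6)
  }
  expect_equal(dice_loss(p, t),
               mean(c(bf_soft(p[, , 1], t1), bf_soft(p[, , 2], t2))),
               tolerance = 1e-12)

  # on binarized predictions the loss is 1 - dice
  for (rep in 1:10) {
    a <- random_mask2d(c(12, 12)); b <- random_mask2d(c(12, 12))
    expect_equal(dice_loss(a, b), 1 - as.numeric(dsc(a, b)), tolerance = 1e-4)
  }
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("backpropagation agrees with central finite differences", {
  set.seed(57)
  cfg <- dehanet_config(n_levels = 2, input_size = c(8, 8), width_scale = 1,
                        base_filters = 2)
  net <- build_dehanet(cfg)
  # push biases off zero so no pre-activation sits exactly on the ReLU kink
  for (nm in grep("_b$", names(net$params), value = TRUE))
    net$params[[nm]] <- net$params[[nm]] + runif(length(net$params[[nm]]), 0.01, 0.05)
  N <- 2
  x <- array(runif(8 * 8 * N), c(8, 8, 1, N))
  r <- array(rbinom(8 * 8 * N, 1, 0.5), c(8, 8, 1, N))
  tg <- array(rbinom(8 * 8 * N, 1, 0.3), c(8, 8, 1, N))
  lossfun <- function(net) {
    fw <- noduleseg:::deha_forward(net, x, r, train = TRUE)
    noduleseg:::nn_dice_loss_grad(fw$prob, tg)$loss
  }
  fw <- noduleseg:::deha_forward(net, x, r, train = TRUE)
  lg <- noduleseg:::nn_dice_loss_grad(fw$prob, tg)
  g <- noduleseg:::deha_backward(net, fw$cache, lg$grad)
  eps <- 1e-6
  for (nm in names(net$params)) {
    k <- sample(length(net$params[[nm]]), 1)
    up <- net; up$params[[nm]][k] <- up$params[[nm]][k] + eps
    dn <- net; dn$params[[nm]][k] <- dn$params[[nm]][k] - eps
    fd <- (lossfun(up) - lossfun(dn)) / (2 * eps)
    expect_equal(g[[nm]][k], fd, tolerance = 1e-3,
                 info = paste("gradient of", nm))
  }
})

test_that("the network can overfit one small batch (wiring check)", {
  set.seed(59)
  net <- build_dehanet(tiny_cfg())
  x <- array(0.3, c(32, 32, 1, 4)); tg <- array(0, c(32, 32, 1, 4))
  r <- array(0, c(32, 32, 1, 4))
  for (i in 1:4) {
    r0 <- 6 + i
    x[r0:(r0 + 8), 10:20, 1, i] <- 0.8
    tg[r0:(r0 + 8), 10:20, 1, i] <- 1
    r[(r0 - 2):(r0 + 10), 8:22, 1, i] <- 1
  }
  vel <- lapply(net$params, function(p) p * 0)
  loss0 <- NA
  for (step in 1:200) {
    fw <- noduleseg:::deha_forward(net, x, r, train = TRUE)
    net$state <- fw$state
    lg <- noduleseg:::nn_dice_loss_grad(fw$prob, tg)
    if (step == 1) loss0 <- lg$loss
    g <- noduleseg:::deha_backward(net, fw$cache, lg$grad)
    for (nm in names(net$params)) {
      vel[[nm]] <- 0.9 * vel[[nm]] - 0.05 * g[[nm]]
      net$params[[nm]] <- net$params[[nm]] + vel[[nm]]
    }
    if (lg$loss < 0.1) break
  }
  expect_lt(lg$loss, 0.1)
  expect_lt(lg$loss, loss0)
})

test_that("training validates inputs, stops early, and returns best weights", {
  set.seed(61)
  net <- build_dehanet(dehanet_config(n_levels = 2, input_size = c(16, 16),
                                      width_scale = 1, base_filters = 2))
  mk <- function(n) lapply(seq_len(n), function(i) {
    tgt <- matrix(0, 16, 16); tgt[6:10, 6:10] <- 1
    list(image = matrix(runif(256, 0.2, 0.4), 16, 16) + 0.4 * tgt,
         roi_mask = noduleseg:::box_mask(c(16, 16), 4, 12, 4, 12),
         target = tgt)
  })
  expect_error(train_dehanet(net, list(), mk(2)), "nonempty")

  tr <- train_dehanet(net, mk(8), mk(2), patience = 0L, max_epochs = 15,
                      lr = 0.05, shuffle_seed = 1)
  h <- tr$history
  expect_true(tr$trained)
  if (nrow(h) < 15) {
    # stopped exactly one epoch after the best validation loss
    expect_equal(nrow(h) - which.min(h$val_loss), 1)
  }
  # descent sanity: training loss improves over the run
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("checkpoints round-trip through disk", {
  set.seed(63)
  net <- build_dehanet(dehanet_config(n_levels = 2, input_size = c(8, 8),
                                      width_scale = 1, base_filters = 2))
  f <- tempfile(fileext = ".rds")
  save_dehanet(net, f)
  back <- load_dehanet(f)
  expect_identical(back$params, net$params)
  expect_identical(back$config, net$config)
  unlink(f)
})
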