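#' Configuration of the dual-encoder hard-attention network
#'
#' The network takes two same-sized 2D inputs — a normalised CT slice and a
#' binary ROI mask — through two identical convolutional encoders, and one
#' decoder that at every level concatenates the matching-level features of
#' both encoders with the previous decoder level. Each encoder level is
#' [conv 3x3 -> ReLU -> batch norm -> 2x2 max pool]; each decoder level is
#' [concat -> conv 3x3 -> ReLU -> batch norm -> 2x nearest upsample], with
#' the last level's upsample replaced by a single-filter 1x1 convolution and
#' a logistic activation giving a per-pixel nodule probability.
#'
#' @param n_levels Encoder/decoder depth (default 4).
#' @param input_size Training input (H, W); each must be divisible by
#'   \code{2^n_levels}. The network itself is fully convolutional, so at
#'   inference any divisible size is accepted (smaller sizes are padded).
#' @param width_scale Multiplier on all filter counts; 0.25 gives a
#'   CPU-friendly desk-scale model, 1 the full-size geometry.
#' @param filter_rule \code{"quadratic"} (default): level \code{n} has
#'   \code{32 * n^2} filters before scaling (32, 128, 288, 512);
#'   \code{"doubling"}: the conventional U-Net ladder \code{32 * 2^(n-1)}.
#' @param base_filters Base filter count (default 32).
#' @param threshold Probability threshold for binarising predictions
#'   (default 0.5).
#' @return A \code{dehanet_config} object.
#' @export
dehanet_config <- function(n_levels = 4L, input_size = c(64L, 64L),
                           width_scale = 1, filter_rule = c("quadratic", "doubling"),
                           base_filters = 32L, threshold = 0.5) {
  filter_rule <- match.arg(filter_rule)
  n_levels <- as.integer(n_levels)
  input_size <- as.integer(input_size)
  if (n_levels < 1L) stop("n_levels must be >= 1")
  if (any(input_size %% 2L^n_levels != 0L))
    stop("input_size (", paste(input_size, collapse = "x"),
         ") must be divisible by 2^n_levels = ", 2L^n_levels)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  n <- seq_len(n_levels)
  raw <- if (filter_rule == "quadratic") base_filters * n^2 else
    base_filters * 2^(n - 1)
  filters <- pmax(1L, as.integer(round(raw * width_scale)))
  structure(list(n_levels = n_levels, input_size = input_size,
                 width_scale = width_scale, filter_rule = filter_rule,
                 base_filters = as.integer(base_filters), filters = filters,
                 threshold = threshold),
            class = "dehanet_config")
}

#' @export
print.dehanet_config <- function(x, ...) {
  cat(sprintf("dual-encoder net: %d levels, filters %s, input %dx%d, threshold %g\n",
              x$n_levels, paste(x$filters, collapse = "/"),
              x$input_size[1], x$input_size[2], x$threshold))
  invisible(x)
}

conv_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

#' Build an untrained dual-encoder network
#'
#' Allocates the weight tensors (He-normal initialised convolutions,
#' unit-gain batch norms) for the architecture described in
#' \code{\link{dehanet_config}}. Uses the current RNG stream; call
#' \code{set.seed} first for reproducible initialisation.
#'
#' @param config A \code{\link{dehanet_config}}.
#' @return An object of class \code{dehanet} holding \code{config},
#'   trainable \code{params}, batch-norm running \code{state}, and a
#'   \code{trained} flag.
#' @export
build_dehanet <- function(config = dehanet_config()) {
  if (!inherits(config, "dehanet_config")) stop("config must be a dehanet_config")
  L <- config$n_levels
  f <- config$filters
  params <- list()
  state <- list()
  add_bn <- function(name, c) {
    params[[paste0(name, "_g")]] <<- rep(1, c)
    params[[paste0(name, "_b")]] <<- rep(0, c)
    state[[paste0(name, "_m")]] <<- rep(0, c)
    state[[paste0(name, "_v")]] <<- rep(1, c)
  }
  for (enc in c("encA", "encB")) {
    for (n in seq_len(L)) {
      cin <- if (n == 1L) 1L else f[n - 1L]
      params[[sprintf("%s_conv%d_w", enc, n)]] <- conv_init(3L, cin, f[n])
      params[[sprintf("%s_conv%d_b", enc, n)]] <- rep(0, f[n])
      add_bn(sprintf("%s_bn%d", enc, n), f[n])
    }
  }
  for (n in rev(seq_len(L))) {
    cin <- 2L * f[n] + if (n == L) 2L * f[L] else f[n + 1L]
    params[[sprintf("dec_conv%d_w", n)]] <- conv_init(3L, cin, f[n])
    params[[sprintf("dec_conv%d_b", n)]] <- rep(0, f[n])
    add_bn(sprintf("dec_bn%d", n), f[n])
  }
  params$out_w <- conv_init(1L, f[1], 1L)
  # background-prior bias: start near "no nodule anywhere", which keeps the
  # dice denominator small and the early gradient signal strong
  params$out_b <- -2
  structure(list(config = config, params = params, state = state,
                 trained = FALSE),
            class = "dehanet")
}

#' @export
print.dehanet <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d trainable parameters, %s\n", dehanet_n_params(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Number of trainable parameters
#' @param net A \code{dehanet}.
#' @return Integer count of trainable scalars (batch-norm running statistics
#'   excluded).
#' @export
dehanet_n_params <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

# Full forward pass. ximg/xroi: H x W x 1 x N. Returns prob and, when
# want_cache, everything the backward pass needs.
deha_forward <- function(net, ximg, xroi, train = FALSE, want_cache = train) {
  L <- net$config$n_levels
  p <- net$params
  st <- net$state
  enc_run <- function(prefix, x) {
    F <- vector("list", L); P <- vector("list", L); cache <- vector("list", L)
    h <- x
    for (n in seq_len(L)) {
      cw <- p[[sprintf("%s_conv%d_w", prefix, n)]]
      z <- .conv2d_fwd(h, cw, p[[sprintf("%s_conv%d_b", prefix, n)]])
      r <- nn_relu_fwd(z)
      bnn <- sprintf("%s_bn%d", prefix, n)
      bn <- nn_bn_fwd(r$y, p[[paste0(bnn, "_g")]], p[[paste0(bnn, "_b")]],
                      st[[paste0(bnn, "_m")]], st[[paste0(bnn, "_v")]], train)
      st[[paste0(bnn, "_m")]] <<- bn$rm
      st[[paste0(bnn, "_v")]] <<- bn$rv
      pool <- nn_maxpool_fwd(bn$y)
      F[[n]] <- bn$y; P[[n]] <- pool$y
      if (want_cache)
        cache[[n]] <- list(x_in = h, keep = r$keep,
                           bn = bn[c("xhat", "ivar", "train")],
                           pool_idx = pool$idx, pool_dim = dim(bn$y))
      h <- pool$y
    }
    list(F = F, P = P, cache = cache)
  }
  A <- enc_run("encA", ximg)
  B <- enc_run("encB", xroi)

  dec_cache <- vector("list", L)
  prev <- nn_up2(nn_concat(list(A$P[[L]], B$P[[L]])))
  for (n in rev(seq_len(L))) {
    xin <- nn_concat(list(A$F[[n]], B$F[[n]], prev))
    z <- .conv2d_fwd(xin, p[[sprintf("dec_conv%d_w", n)]],
                     p[[sprintf("dec_conv%d_b", n)]])
    r <- nn_relu_fwd(z)
    bnn <- sprintf("dec_bn%d", n)
    bn <- nn_bn_fwd(r$y, p[[paste0(bnn, "_g")]], p[[paste0(bnn, "_b")]],
                    st[[paste0(bnn, "_m")]], st[[paste0(bnn, "_v")]], train)
    st[[paste0(bnn, "_m")]] <- bn$rm
    st[[paste0(bnn, "_v")]] <- bn$rv
    if (want_cache)
      dec_cache[[n]] <- list(x_in = xin, keep = r$keep,
                             bn = bn[c("xhat", "ivar", "train")],
                             sizes = c(dim(A$F[[n]])[3], dim(B$F[[n]])[3],
                                       dim(prev)[3]))
    prev <- if (n > 1L) nn_up2(bn$y) else bn$y
  }
  logits <- .conv2d_fwd(prev, p$out_w, p$out_b)
  prob <- nn_sigmoid(logits)
  cache <- if (want_cache)
    list(A = A, B = B, dec = dec_cache, head_in = prev, prob = prob) else NULL
  list(prob = prob, cache = cache, state = st)
}

# Backward pass from dL/dprob; returns gradient list named like params.
deha_backward <- function(net, cache, dprob) {
  L <- net$config$n_levels
  p <- net$params
  g <- list()
  dlogits <- dprob * cache$prob * (1 - cache$prob)
  cb <- .conv2d_bwd(cache$head_in, p$out_w, dlogits)
  g$out_w <- cb$dw; g$out_b <- cb$db
  dprev <- cb$dx

  dF_A <- vector("list", L); dF_B <- vector("list", L)
  dP_bottleneck <- NULL
  for (n in seq_len(L)) {
    dc <- cache$dec[[n]]
    if (n > 1L) dprev <- nn_up2_bwd(dprev)
    bnn <- sprintf("dec_bn%d", n)
    bb <- nn_bn_bwd(dprev, dc$bn, p[[paste0(bnn, "_g")]])
    g[[paste0(bnn, "_g")]] <- bb$dgamma; g[[paste0(bnn, "_b")]] <- bb$dbeta
    dz <- nn_relu_bwd(bb$dx, dc$keep)
    cb <- .conv2d_bwd(dc$x_in, p[[sprintf("dec_conv%d_w", n)]], dz)
    g[[sprintf("dec_conv%d_w", n)]] <- cb$dw
    g[[sprintf("dec_conv%d_b", n)]] <- cb$db
    parts <- nn_split_channels(cb$dx, dc$sizes)
    dF_A[[n]] <- parts[[1]]; dF_B[[n]] <- parts[[2]]
    if (n == L) {
      dbott <- nn_up2_bwd(parts[[3]])
      fL <- dim(dbott)[3] / 2L
      dP_bottleneck <- nn_split_channels(dbott, c(fL, fL))
    } else {
      dprev <- parts[[3]]
    }
  }

  enc_back <- function(prefix, enc, dF, dP_last) {
    dpool_next <- NULL
    for (n in rev(seq_len(L))) {
      ec <- enc$cache[[n]]
      dpool <- if (n == L) dP_last else dpool_next
      dy <- nn_maxpool_bwd(dpool, ec$pool_dim, ec$pool_idx) + dF[[n]]
      bnn <- sprintf("%s_bn%d", prefix, n)
      bb <- nn_bn_bwd(dy, ec$bn, p[[paste0(bnn, "_g")]])
      g[[paste0(bnn, "_g")]] <<- bb$dgamma
      g[[paste0(bnn, "_b")]] <<- bb$dbeta
      dz <- nn_relu_bwd(bb$dx, ec$keep)
      cb <- .conv2d_bwd(ec$x_in, p[[sprintf("%s_conv%d_w", prefix, n)]], dz)
      g[[sprintf("%s_conv%d_w", prefix, n)]] <<- cb$dw
      g[[sprintf("%s_conv%d_b", prefix, n)]] <<- cb$db
      dpool_next <- cb$dx
    }
  }
  enc_back("encA", cache$A, dF_A, dP_bottleneck[[1]])
  enc_back("encB", cache$B, dF_B, dP_bottleneck[[2]])
  g
}

#' Soft dice loss
#'
#' Mean over the batch of \code{1 - (2 * sum(p * t) + eps) /
#' (sum(p) + sum(t) + eps)}: 0 for perfect overlap, ~1 for disjoint masks.
#' The soft intersection \code{sum(p * t)} makes the loss differentiable in
#' the predicted probabilities.
#'
#' @param pred Array of probabilities, last dimension indexing samples
#'   (a single 2D matrix is treated as a batch of one).
#' @param target Binary array of the same shape.
#' @param eps Smoothing constant (default 1e-6).
#' @return Scalar loss in \eqn{[0, 1]} (up to \code{eps}).
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ")
  if (is.matrix(pred)) { dim(pred) <- c(dim(pred), 1L); dim(target) <- dim(pred) }
  nn_dice_loss_grad(pred, target, eps)$loss
}

stack_samples <- function(samples, field, shape) {
  arr <- array(0, c(shape, 1L, length(samples)))
  for (i in seq_along(samples)) arr[, , 1L, i] <- samples[[i]][[field]]
  arr
}

eval_loss <- function(net, X, R, T, batch = 8L, eps = 1e-6) {
  N <- dim(X)[4]
  tot <- 0
  for (s in seq(1L, N, by = batch)) {
    e <- min(s + batch - 1L, N)
    fw <- deha_forward(net, X[, , , s:e, drop = FALSE],
                       R[, , , s:e, drop = FALSE], train = FALSE,
                       want_cache = FALSE)
    tot <- tot + nn_dice_loss_grad(fw$prob, T[, , , s:e, drop = FALSE],
                                   eps = eps)$loss * (e - s + 1L)
  }
  tot / N
}

#' Train the network with SGD and early stopping
#'
#' Minimises \code{\link{dice_loss}} by stochastic gradient descent with
#' momentum, monitoring the validation loss after every epoch and stopping
#' once it has failed to improve for \code{patience} consecutive epochs; the
#' weights from the best validation epoch are returned. Defaults follow the
#' reference training recipe: learning rate 0.001, momentum 0.9, batch
#' size 8, patience 10.
#'
#' @param net A \code{\link{build_dehanet}} network.
#' @param samples,val_samples Lists of training samples as produced by
#'   \code{\link{sample_training_set}} (fields \code{image},
#'   \code{roi_mask}, \code{target}).
#' @param lr,momentum,batch_size,patience,max_epochs SGD hyperparameters.
#' @param loss_eps Smoothing constant of the training loss (default 1, the
#'   conventional choice). A near-zero smoothing silently removes the
#'   gradient of nodule-free samples (their numerator collapses to
#'   \code{eps}), so the network would never learn to suppress predictions
#'   on non-nodular slices.
#' @param shuffle_seed Optional integer seed for the per-epoch shuffling.
#' @param log_csv Optional path; per-epoch losses are appended as CSV.
#' @param verbose Print per-epoch losses.
#' @return The trained network with a \code{history} data frame attached
#'   (\code{net$history}: epoch, train_loss, val_loss).
#' @export
train_dehanet <- function(net, samples, val_samples, lr = 0.001,
                          momentum = 0.9, batch_size = 8L, patience = 10L,
                          max_epochs = 100L, loss_eps = 1, shuffle_seed = NULL,
                          log_csv = NULL, verbose = FALSE) {
  if (length(samples) == 0L || length(val_samples) == 0L)
    stop("training and validation sets must be nonempty")
  shape <- dim(samples[[1]]$image)
  X <- stack_samples(samples, "image", shape)
  R <- stack_samples(samples, "roi_mask", shape)
  T <- stack_samples(samples, "target", shape)
  Xv <- stack_samples(val_samples, "image", shape)
  Rv <- stack_samples(val_samples, "roi_mask", shape)
  Tv <- stack_samples(val_samples, "target", shape)
  N <- length(samples)

  vel <- lapply(net$params, function(p) p * 0)
  best <- list(loss = Inf, params = net$params, state = net$state)
  wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  if (!is.null(shuffle_seed)) set.seed(shuffle_seed)

  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0
    for (s in seq(1L, N, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, N)]
      fw <- deha_forward(net, X[, , , idx, drop = FALSE],
                         R[, , , idx, drop = FALSE], train = TRUE)
      net$state <- fw$state
      lg <- nn_dice_loss_grad(fw$prob, T[, , , idx, drop = FALSE],
                              eps = loss_eps)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate")
      grads <- deha_backward(net, fw$cache, lg$grad)
      for (nm in names(net$params)) {
        vel[[nm]] <- momentum * vel[[nm]] - lr * grads[[nm]]
        net$params[[nm]] <- net$params[[nm]] + vel[[nm]]
      }
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    ep_loss <- ep_loss / N
    val <- eval_loss(net, Xv, Rv, Tv, batch = batch_size, eps = loss_eps)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = val))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, ep_loss, val))
    if (!is.null(log_csv))
      write.csv(history, log_csv, row.names = FALSE)
    if (val < best$loss - 1e-6) {
      best <- list(loss = val, params = net$params, state = net$state)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > patience) break
    }
  }
  net$params <- best$params
  net$state <- best$state
  net$trained <- TRUE
  net$history <- history
  net
}

#' Segment one slice
#'
#' Generic over segmenter types: the trained network
#' (\code{\link{build_dehanet}}) or the intensity-thresholding oracle
#' (\code{\link{threshold_segmenter}}) used for algorithmic testing. Returns
#' the per-pixel probability map and the binarised mask. The hard-attention
#' contract is enforced at the output: pixels outside the bounding box of
#' \code{roi_mask} are forced to 0 in the binary mask, so an all-zero ROI
#' yields an all-zero mask.
#'
#' @param segmenter A \code{dehanet} or \code{threshold_segmenter}.
#' @param image Normalised 2D slice (values in [0, 1]).
#' @param roi_mask Binary 2D matrix of the same shape.
#' @param ... Passed to methods.
#' @return A \code{slice_segmentation}: list \code{(prob, mask, threshold)}.
#' @export
segment_slice <- function(segmenter, image, roi_mask, ...) {
  UseMethod("segment_slice")
}

apply_hard_attention <- function(prob, roi_mask, threshold) {
  mask <- (prob >= threshold) * 1
  bb <- mask_bbox(roi_mask)
  if (is.null(bb)) {
    mask[] <- 0
  } else {
    keep <- matrix(0, nrow(mask), ncol(mask))
    keep[bb$r0:bb$r1, bb$c0:bb$c1] <- 1
    mask <- mask * keep
  }
  structure(list(prob = prob, mask = mask, threshold = threshold),
            class = "slice_segmentation")
}

#' @rdname segment_slice
#' @export
segment_slice.dehanet <- function(segmenter, image, roi_mask, ...) {
  if (!identical(dim(image), dim(roi_mask)))
    stop("image and roi_mask shapes differ")
  if (!segmenter$trained)
    warning("segmenting with untrained network weights")
  div <- 2L^segmenter$config$n_levels
  d <- dim(image)
  dp <- as.integer(ceiling(d / div) * div)
  xi <- matrix(0, dp[1], dp[2]); xi[seq_len(d[1]), seq_len(d[2])] <- image
  xr <- matrix(0, dp[1], dp[2]); xr[seq_len(d[1]), seq_len(d[2])] <- roi_mask
  dim(xi) <- c(dp, 1L, 1L); dim(xr) <- c(dp, 1L, 1L)
  fw <- deha_forward(segmenter, xi, xr, train = FALSE, want_cache = FALSE)
  prob <- fw$prob[seq_len(d[1]), seq_len(d[2]), 1L, 1L]
  apply_hard_attention(prob, roi_mask, segmenter$config$threshold)
}

#' Intensity-thresholding oracle segmenter
#'
#' A deterministic stand-in segmenter for algorithm-level tests: inside the
#' ROI's bounding box it labels every pixel whose normalised intensity
#' reaches \code{level}. On noise-free phantoms whose nodule is the only
#' structure above \code{level}, it recovers the ground truth exactly,
#' letting the ROI-propagation and multi-view machinery be validated
#' independently of any learned weights.
#'
#' @param level Intensity threshold in (0, 1); default 0.55, midway between
#'   the phantom background (~0.3) and nodule (~0.8) after windowing.
#' @return A \code{threshold_segmenter}.
#' @export
threshold_segmenter <- function(level = 0.55) {
  stopifnot(level > 0, level < 1)
  structure(list(level = level, threshold = level),
            class = "threshold_segmenter")
}

#' @rdname segment_slice
#' @export
segment_slice.threshold_segmenter <- function(segmenter, image, roi_mask, ...) {
  if (!identical(dim(image), dim(roi_mask)))
    stop("image and roi_mask shapes differ")
  apply_hard_attention(image, roi_mask, segmenter$level)
}

#' Save / load network weights
#'
#' Checkpoints are plain RDS files holding the full \code{dehanet} object
#' (config, weights, batch-norm state, history).
#'
#' @param net A \code{dehanet}.
#' @param path Checkpoint path.
#' @export
save_dehanet <- function(net, path) {
  stopifnot(inherits(net, "dehanet"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_dehanet
#' @export
load_dehanet <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "dehanet")) stop("not a dehanet checkpoint: ", path)
  net
}
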