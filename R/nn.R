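# Internal layer primitives for the dual-encoder network. Activations are
# H x W x C x N arrays throughout; convolutions live in src/convnet.cpp,
# everything else is vectorised R. Each *_fwd returns what its *_bwd needs.

nn_relu_fwd <- function(x) {
  keep <- x > 0
  list(y = x * keep, keep = keep)
}

nn_relu_bwd <- function(dy, keep) dy * keep

# Batch normalisation per channel (over H, W, N), biased batch variance,
# running statistics for eval mode.
nn_bn_fwd <- function(x, gamma, beta, rm, rv, train, momentum = 0.9,
                      eps = 1e-5) {
  d <- dim(x)
  M <- d[1] * d[2] * d[4]
  if (train) {
    s1 <- rowSums(colSums(x, dims = 2L))        # per-channel sums
    s2 <- rowSums(colSums(x * x, dims = 2L))
    m <- s1 / M
    v <- pmax(s2 / M - m^2, 0)
    rm_new <- momentum * rm + (1 - momentum) * m
    rv_new <- momentum * rv + (1 - momentum) * v
  } else {
    m <- rm; v <- rv; rm_new <- rm; rv_new <- rv
  }
  ivar <- 1 / sqrt(v + eps)
  hw <- d[1] * d[2]
  xhat <- (x - rep(m, each = hw)) * rep(ivar, each = hw)
  y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  list(y = y, xhat = xhat, ivar = ivar, rm = rm_new, rv = rv_new,
       train = train)
}

nn_bn_bwd <- function(dy, cache, gamma) {
  d <- dim(dy)
  hw <- d[1] * d[2]
  M <- hw * d[4]
  dxhat <- dy * rep(gamma, each = hw)
  dgamma <- rowSums(colSums(dy * cache$xhat, dims = 2L))
  dbeta <- rowSums(colSums(dy, dims = 2L))
  if (cache$train) {
    s1 <- rowSums(colSums(dxhat, dims = 2L))
    s2 <- gamma * dgamma  # == sum(dxhat * xhat)
    dx <- (dxhat - rep(s1 / M, each = hw) -
             cache$xhat * rep(s2 / M, each = hw)) * rep(cache$ivar, each = hw)
  } else {
    dx <- dxhat * rep(cache$ivar, each = hw)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

nn_maxpool_fwd <- function(x) .maxpool2_fwd(x)

nn_maxpool_bwd <- function(dy, x_dim, idx) {
  dx <- array(0, x_dim)
  dx[idx] <- dy
  dx
}

# Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
nn_up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

nn_up2_bwd <- function(dy) {
  d <- dim(dy)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  dy[ro, co, , , drop = FALSE] + dy[re, co, , , drop = FALSE] +
    dy[ro, ce, , , drop = FALSE] + dy[re, ce, , , drop = FALSE]
}

# Concatenate along the channel axis.
nn_concat <- function(parts) {
  d1 <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[3]
    out[, , at + seq_len(cp), ] <- p
    at <- at + cp
  }
  out
}

nn_split_channels <- function(dy, sizes) {
  at <- 0L
  lapply(sizes, function(cp) {
    out <- dy[, , at + seq_len(cp), , drop = FALSE]
    at <<- at + cp
    out
  })
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

# Soft dice loss over a batch (Eq.-style: mean over samples of
# 1 - (2*sum(p*t)+eps) / (sum(p)+sum(t)+eps)) and its gradient w.r.t. p.
nn_dice_loss_grad <- function(pred, target, eps = 1e-6) {
  d <- dim(pred)
  N <- d[length(d)]
  pm <- matrix(pred, ncol = N)
  tm <- matrix(target, ncol = N)
  inter <- colSums(pm * tm)
  denom <- colSums(pm) + colSums(tm) + eps
  num <- 2 * inter + eps
  loss <- mean(1 - num / denom)
  # d/dp_i of -(2*sum(pt)+eps)/D with D depending on sum(p)
  gm <- sweep(tm, 2, -2 / denom, "*") + matrix(num / denom^2, nrow(tm), N,
                                               byrow = TRUE)
  gm <- gm / N
  grad <- array(gm, d)
  list(loss = loss, grad = grad)
}
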