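# Brute-force oracles, independent of the package implementations.

# Pixel-counting overlap metrics: loop over every voxel.
bf_counts <- function(pred, ref) {
  tp <- 0; np <- 0; nr <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && ref[i] == 1) tp <- tp + 1
    if (pred[i] == 1) np <- np + 1
    if (ref[i] == 1) nr <- nr + 1
  }
  list(tp = tp, np = np, nr = nr)
}
bf_dsc <- function(pred, ref) {
  ct <- bf_counts(pred, ref)
  2 * ct$tp / (ct$np + ct$nr)
}
bf_sen <- function(pred, ref) { ct <- bf_counts(pred, ref); ct$tp / ct$nr }
bf_ppv <- function(pred, ref) { ct <- bf_counts(pred, ref); ct$tp / ct$np }

# Brute-force adaptive-ROI margin rule: scan for the bbox, add
# ceiling(rt * extent) per side, clip, fill.
bf_roi <- function(seg, rt) {
  d <- dim(seg)
  r0 <- Inf; r1 <- -Inf; c0 <- Inf; c1 <- -Inf
  for (r in seq_len(d[1])) for (c in seq_len(d[2]))
    if (seg[r, c] == 1) {
      r0 <- min(r0, r); r1 <- max(r1, r)
      c0 <- min(c0, c); c1 <- max(c1, c)
    }
  if (!is.finite(r0)) return(matrix(0, d[1], d[2]))
  mr <- ceiling(rt * (r1 - r0 + 1)); mc <- ceiling(rt * (c1 - c0 + 1))
  out <- matrix(0, d[1], d[2])
  out[max(1, r0 - mr):min(d[1], r1 + mr),
      max(1, c0 - mc):min(d[2], c1 + mc)] <- 1
  out
}

random_mask2d <- function(shape = c(24, 24), p = 0.15) {
  m <- matrix(rbinom(prod(shape), 1, p), shape[1], shape[2])
  if (sum(m) == 0) m[sample(length(m), 1)] <- 1
  m
}

# A noiseless, textureless, vessel-free phantom whose only structure above
# the oracle threshold is the nodule: thresholding recovers it exactly.
clean_phantom_spec <- function(volume_shape = c(36L, 48L, 48L),
                               spacing = c(0.7, 0.7, 0.7),
                               semi_axes_mm = c(4, 5, 3),
                               lobulation = 0, rotation = 0, seed = 11L, ...) {
  phantom_spec(volume_shape = volume_shape, spacing = spacing,
               semi_axes_mm = semi_axes_mm, lobulation = lobulation,
               rotation = rotation, n_vessels = 0L, texture_amp = 0,
               noise_sd = 0, seed = seed, ...)
}
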