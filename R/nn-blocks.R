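# Shared building blocks for the three encoder-decoder networks: inception
# blocks (parallel 1x1 / 3x3 / 5x5 / pooled paths with 1x1 reductions, each
# conv followed by per-channel normalisation and ReLU), reflection padding
# and patch normalisation.

# -- parameter construction --------------------------------------------------

add_conv_bn <- function(params, name, k, cin, cout) {
  params <- nn_param_conv(params, name, k, cin, cout)
  nn_param_norm(params, name, cout)
}

# four-path inception: 1x1 | 1x1->3x3 | 1x1->5x5 | boxpool->1x1
add_incep4 <- function(params, name, cin, width) {
  w <- max(1L, as.integer(round(width / 4)))
  red <- max(1L, as.integer(round(w / 2)))
  params <- add_conv_bn(params, paste0(name, ".p1"), 1, cin, w)
  params <- add_conv_bn(params, paste0(name, ".p2r"), 1, cin, red)
  params <- add_conv_bn(params, paste0(name, ".p2"), 3, red, w)
  params <- add_conv_bn(params, paste0(name, ".p3r"), 1, cin, red)
  params <- add_conv_bn(params, paste0(name, ".p3"), 5, red, w)
  params <- add_conv_bn(params, paste0(name, ".p4"), 1, cin, w)
  attr(params, paste0(name, ".out")) <- 4L * w
  params
}

t_incep4 <- function(tp, x, ids, name, cin) {
  box <- t_box3(tp, x, cin)
  p1 <- t_conv_bn_relu(tp, x, ids, paste0(name, ".p1"))
  p2 <- t_conv_bn_relu(tp, t_conv_bn_relu(tp, x, ids, paste0(name, ".p2r")),
                       ids, paste0(name, ".p2"))
  p3 <- t_conv_bn_relu(tp, t_conv_bn_relu(tp, x, ids, paste0(name, ".p3r")),
                       ids, paste0(name, ".p3"))
  p4 <- t_conv_bn_relu(tp, box, ids, paste0(name, ".p4"))
  t_concat(tp, c(p1, p2, p3, p4))
}

# two-path inception (3x3 and 1x1 kernels only)
add_incep2 <- function(params, name, cin, width) {
  w <- max(1L, as.integer(round(width / 2)))
  red <- max(1L, as.integer(round(w / 2)))
  params <- add_conv_bn(params, paste0(name, ".p1"), 1, cin, w)
  params <- add_conv_bn(params, paste0(name, ".p2r"), 1, cin, red)
  params <- add_conv_bn(params, paste0(name, ".p2"), 3, red, w)
  attr(params, paste0(name, ".out")) <- 2L * w
  params
}

t_incep2 <- function(tp, x, ids, name) {
  p1 <- t_conv_bn_relu(tp, x, ids, paste0(name, ".p1"))
  p2 <- t_conv_bn_relu(tp, t_conv_bn_relu(tp, x, ids, paste0(name, ".p2r")),
                       ids, paste0(name, ".p2"))
  t_concat(tp, c(p1, p2))
}

# fixed (non-learned) 3x3 box filter, identity across channels
t_box3 <- function(tp, x, cin) {
  w <- array(0, dim = c(3, 3, cin, cin))
  for (c in seq_len(cin)) w[, , c, c] <- 1 / 9
  t_conv(tp, x, tp_leaf(tp, w), tp_leaf(tp, numeric(cin)))
}

# -- raster plumbing ---------------------------------------------------------

# reflect-pad a (H,W,C) array (or matrix) on each side
pad_reflect <- function(x, top, bottom, left, right) {
  m <- length(dim(x)) == 2
  if (m) dim(x) <- c(dim(x), 1)
  H <- dim(x)[1]; W <- dim(x)[2]
  ri <- c(if (top > 0) (top + 1):2 else integer(0), 1:H,
          if (bottom > 0) (H - 1):(H - bottom) else integer(0))
  ci <- c(if (left > 0) (left + 1):2 else integer(0), 1:W,
          if (right > 0) (W - 1):(W - right) else integer(0))
  out <- x[ri, ci, , drop = FALSE]
  if (m) dim(out) <- dim(out)[1:2]
  out
}

# pad to a multiple of 2^depth (reflection); returns padded array + crop info
pad_to_multiple <- function(x, mult) {
  H <- dim(x)[1]; W <- dim(x)[2]
  ph <- (mult - H %% mult) %% mult
  pw <- (mult - W %% mult) %% mult
  list(x = pad_reflect(x, 0, ph, 0, pw), H = H, W = W)
}

# zero-mean / unit-sd standardisation of a tile array
normalize_patch <- function(x) {
  s <- stats::sd(x)
  if (s < 1e-8) s <- 1
  (x - mean(x)) / s
}

# 2x average-downsample of a (H,W,C) array, repeated `times`
downsample2 <- function(x, times = 1) {
  for (i in seq_len(times)) x <- cpp_avgpool2_fw(x)
  x
}

# 2x average-downsample of a numeric matrix (used for aux-resolution targets)
downsample2_mat <- function(m, times = 1) {
  x <- array(m, dim = c(dim(m), 1))
  for (i in seq_len(times)) x <- cpp_avgpool2_fw(x)
  matrix(x, dim(x)[1], dim(x)[2])
}
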