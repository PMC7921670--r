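# Minimal reverse-mode autodiff over (H, W, C) arrays, backed by the C++
# convolution / pooling / transpose-convolution kernels in src/convops.cpp.
# Only the ops the networks in this package need are provided. All of this is
# internal; models expose high-level build/train/predict functions.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = integer(), backfn = NULL) {
  tp$n <- tp$n + 1L
  tp$nodes[[tp$n]] <- list(value = value, parents = parents, backfn = backfn)
  tp$n
}

tp_leaf <- function(tp, value) tp_push(tp, value)

tp_value <- function(tp, id) {
  force(id) # id may itself push onto the tape; resolve before indexing
  tp$nodes[[id]]
}$value

# Backward pass from a scalar loss node; returns list of gradients indexed by
# node id for the requested leaf ids.
tp_backward <- function(tp, loss_id, wanted) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (id in seq(loss_id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (is.null(nd$backfn) || !length(nd$parents)) next
    pg <- nd$backfn(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads[wanted]
}

t_conv <- function(tp, x, w, b) {
  xv <- tp_value(tp, x); wv <- tp_value(tp, w); bv <- tp_value(tp, b)
  y <- cpp_conv2d_fw(xv, wv, bv)
  tp_push(tp, y, c(x, w, b), function(gy) {
    r <- cpp_conv2d_bw(xv, wv, gy)
    list(r$gx, r$gw, r$gb)
  })
}

t_tconv <- function(tp, x, w, b) {
  xv <- tp_value(tp, x); wv <- tp_value(tp, w); bv <- tp_value(tp, b)
  y <- cpp_tconv2_fw(xv, wv, bv)
  tp_push(tp, y, c(x, w, b), function(gy) {
    r <- cpp_tconv2_bw(xv, wv, gy)
    list(r$gx, r$gw, r$gb)
  })
}

t_avgpool <- function(tp, x) {
  y <- cpp_avgpool2_fw(tp_value(tp, x))
  tp_push(tp, y, x, function(gy) list(cpp_avgpool2_bw(gy)))
}

t_relu <- function(tp, x) {
  xv <- tp_value(tp, x)
  y <- pmax(xv, 0)
  dim(y) <- dim(xv)
  tp_push(tp, y, x, function(gy) list(gy * (xv > 0)))
}

t_sigmoid <- function(tp, x) {
  y <- 1 / (1 + exp(-tp_value(tp, x)))
  tp_push(tp, y, x, function(gy) list(gy * y * (1 - y)))
}

t_concat <- function(tp, ids) {
  vals <- lapply(ids, tp_value, tp = tp)
  d <- dim(vals[[1]])
  ch <- vapply(vals, function(v) dim(v)[3], 0)
  y <- array(unlist(vals, use.names = FALSE), dim = c(d[1], d[2], sum(ch)))
  tp_push(tp, y, ids, function(gy) {
    out <- vector("list", length(ids))
    off <- 0L
    for (k in seq_along(ids)) {
      out[[k]] <- gy[, , off + seq_len(ch[k]), drop = FALSE]
      off <- off + ch[k]
    }
    out
  })
}

# per-channel normalisation over the spatial plane (batch-free), learnable
# scale gamma and shift beta, each length C
t_chnorm <- function(tp, x, gamma, beta, eps = 1e-5) {
  xv <- tp_value(tp, x)
  d <- dim(xv); N <- d[1] * d[2]; C <- d[3]
  xm <- matrix(xv, N, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  g <- tp_value(tp, gamma); b <- tp_value(tp, beta)
  y <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  dim(y) <- d
  tp_push(tp, y, c(x, gamma, beta), function(gy) {
    gym <- matrix(gy, N, C)
    dgamma <- colSums(gym * xhat)
    dbeta <- colSums(gym)
    dxhat <- sweep(gym, 2, g, `*`)
    # dx = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`), 2, istd, `*`)
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# weighted binary cross-entropy on logits: mean(w * (softplus(z) - t*z))
t_wbce <- function(tp, z, target, w) {
  zv <- tp_value(tp, z)
  n <- length(zv)
  if (length(target) == n) dim(target) <- dim(zv)
  if (length(w) == n) dim(w) <- dim(zv)
  sp <- ifelse(zv > 30, zv, log1p(exp(pmin(zv, 30))))
  loss <- sum(w * (sp - target * zv)) / n
  tp_push(tp, loss, z, function(gy) {
    p <- 1 / (1 + exp(-zv))
    list(gy * w * (p - target) / n)
  })
}

# weighted mean squared error on an activation map
t_wmse <- function(tp, p, target, w) {
  pv <- tp_value(tp, p)
  n <- length(pv)
  loss <- sum(w * (pv - target)^2) / n
  tp_push(tp, loss, p, function(gy) list(gy * 2 * w * (pv - target) / n))
}

t_add_scalar <- function(tp, ids, coefs) {
  y <- 0
  for (k in seq_along(ids)) y <- y + coefs[k] * tp_value(tp, ids[[k]])
  tp_push(tp, y, unlist(ids), function(gy) as.list(gy * coefs))
}

# dense layer on a flattened vector: y = W x + b   (W: nout x nin)
t_dense <- function(tp, x, w, b) {
  xd <- dim(tp_value(tp, x))
  xv <- as.vector(tp_value(tp, x))
  wv <- tp_value(tp, w)
  y <- as.vector(wv %*% xv + tp_value(tp, b))
  tp_push(tp, y, c(x, w, b), function(gy) {
    gx <- as.vector(crossprod(wv, gy))
    if (!is.null(xd)) dim(gx) <- xd
    list(gx, outer(gy, xv), gy)
  })
}

# softmax cross-entropy on a logit vector against an integer label
t_softmax_ce <- function(tp, z, label) {
  zv <- tp_value(tp, z)
  zs <- zv - max(zv)
  p <- exp(zs) / sum(exp(zs))
  loss <- -log(max(p[label], 1e-12))
  tp_push(tp, loss, z, function(gy) {
    g <- p
    g[label] <- g[label] - 1
    list(gy * g)
  })
}

# ---- parameter helpers ------------------------------------------------------

nn_he_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

nn_param_conv <- function(params, name, k, cin, cout) {
  params[[paste0(name, ".w")]] <- nn_he_conv(k, cin, cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

nn_param_norm <- function(params, name, c) {
  params[[paste0(name, ".g")]] <- rep(1, c)
  params[[paste0(name, ".beta")]] <- rep(0, c)
  params
}

nn_param_tconv <- function(params, name, cin, cout) {
  params[[paste0(name, ".w")]] <- array(
    stats::rnorm(4 * cin * cout, sd = sqrt(2 / (4 * cin))),
    dim = c(2, 2, cin, cout))
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

nn_param_dense <- function(params, name, nin, nout) {
  params[[paste0(name, ".w")]] <- matrix(
    stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nout, nin)
  params[[paste0(name, ".b")]] <- numeric(nout)
  params
}

# leaves for all parameters; returns env mapping name -> node id
nn_leaves <- function(tp, params) {
  ids <- vapply(params, function(p) tp_leaf(tp, p), 0L)
  names(ids) <- names(params)
  ids
}

# composite blocks used by all networks -------------------------------------

t_conv_bn_relu <- function(tp, x, ids, name) {
  h <- t_conv(tp, x, ids[[paste0(name, ".w")]], ids[[paste0(name, ".b")]])
  h <- t_chnorm(tp, h, ids[[paste0(name, ".g")]], ids[[paste0(name, ".beta")]])
  t_relu(tp, h)
}

# ---- Adam ------------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# gradient collection for a param leaf map
nn_grads <- function(tp, loss_id, ids) {
  g <- tp_backward(tp, loss_id, as.integer(ids))
  names(g) <- names(ids)
  g
}
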