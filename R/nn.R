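# Minimal CPU neural-network primitives for the segment encoder: 2-D
# convolution (im2col + BLAS matmul), batch normalization, ReLU, 2x2 average
# pooling, global average pooling, dense layers, Adam, and a numerically
# stable binary cross-entropy on logits.
#
# Internal tensor layout is channel-first, (C, H, W, N): with channels along
# the fastest-varying dimension, im2col blocks, batch-norm statistics and all
# reshapes are plain contiguous operations and no array permutation is needed
# anywhere in the conv path. The backward-data pass is itself a convolution
# with spatially flipped, channel-transposed kernels rather than a scatter
# loop. All gradients are verified against finite differences in the tests.

nn_pad <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

# im2col: rows enumerate (channel, kernel row, kernel col) with channel
# fastest; columns enumerate (out row, out col, batch). Implemented as one
# vectorised gather with a memoised linear-index table per input geometry.
.nn_cache <- new.env(parent = emptyenv())

im2col_index <- function(d, k) {
  # keyed by geometry WITHOUT the batch size: one bounded entry per layer
  # shape, holding the single-sample index table plus the expanded index for
  # the most recently seen batch size (batches mostly share one size).
  key <- paste(c(d[1:3], k), collapse = "x")
  n <- d[4]
  hit <- .nn_cache[[key]]
  if (!is.null(hit) && hit$n == n) return(hit$idx)
  if (is.null(hit)) {
    n_ch <- d[1]
    hp <- d[2]
    wp <- d[3]
    out_h <- hp - k + 1L
    out_w <- wp - k + 1L
    b <- matrix(0L, nrow = n_ch * k * k, ncol = out_h * out_w)
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        colbase <- as.integer(outer(
          n_ch * (seq_len(out_h) + di - 2L),
          n_ch * hp * (seq_len(out_w) + dj - 2L), `+`
        ))
        b[n_ch * ((di - 1L) + k * (dj - 1L)) + seq_len(n_ch), ] <-
          outer(seq_len(n_ch), colbase, `+`)
      }
    }
    hit <- list(base = as.vector(b), per = d[1] * d[2] * d[3], n = -1L)
  }
  hit$idx <- rep(hit$base, n) +
    rep.int(hit$per * (seq_len(n) - 1L), rep.int(length(hit$base), n))
  hit$n <- n
  .nn_cache[[key]] <- hit
  hit$idx
}

nn_im2col <- function(xp, k, out_h, out_w) {
  d <- dim(xp)
  cols <- xp[im2col_index(d, k)]
  dim(cols) <- c(d[1] * k * k, out_h * out_w * d[4])
  cols
}

conv2d_forward <- function(x, w, b, k, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  out_h <- d[2] + 2L * pad - k + 1L
  out_w <- d[3] + 2L * pad - k + 1L
  cols <- nn_im2col(nn_pad(x, pad), k, out_h, out_w)
  y <- w %*% cols + b
  dim(y) <- c(nrow(w), out_h, out_w, d[4])
  list(out = y, cache = list(cols = cols, dim_in = d, k = k, pad = pad))
}

# Rearrange a (C_out, C_in*k*k) weight matrix into the (C_in, C_out*k*k)
# backward-data kernel: channels transposed, kernel flipped 180 degrees.
flip_weights <- function(w, k) {
  c_out <- nrow(w)
  c_in <- ncol(w) %/% (k * k)
  arr <- array(w, dim = c(c_out, c_in, k, k))
  arr <- arr[, , k:1, k:1, drop = FALSE]
  wf <- aperm(arr, c(2, 1, 3, 4))
  dim(wf) <- c(c_in, c_out * k * k)
  wf
}

conv2d_backward <- function(dy, w, cache) {
  k <- cache$k
  d <- cache$dim_in
  c_out <- dim(dy)[1]
  dym <- dy
  dim(dym) <- c(c_out, length(dy) %/% c_out)
  dw <- tcrossprod(dym, cache$cols)
  db <- rowSums(dym)
  # backward-data: convolve dy with the flipped kernel at complement padding
  dx <- conv2d_forward(dy, flip_weights(w, k), 0, k, pad = k - 1L - cache$pad)$out
  dim(dx) <- d
  list(dx = dx, dw = dw, db = db)
}

# 1x1 projection convolution: a channel-mixing matrix multiply.
proj_forward <- function(x, w) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1], length(x) %/% d[1])
  y <- w %*% xm
  dim(y) <- c(nrow(w), d[2], d[3], d[4])
  list(out = y, cache = list(xm = xm, dim_in = d))
}

proj_backward <- function(dy, w, cache) {
  d <- cache$dim_in
  dym <- dy
  dim(dym) <- c(dim(dy)[1], length(dy) %/% dim(dy)[1])
  dw <- tcrossprod(dym, cache$xm)
  dx <- crossprod(w, dym)
  dim(dx) <- d
  list(dx = dx, dw = dw)
}

BN_EPS <- 1e-5

# Per-channel batch norm; with channels first, statistics are rowMeans and
# the scale/shift recycle along the first dimension with no sweeps.
bn_forward <- function(x, gamma, beta, running, training, momentum = 0.1) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1], length(x) %/% d[1])
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- xm - mu
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * invstd
  y <- xhat * gamma + beta
  dim(y) <- d
  list(out = y, running = running,
    cache = list(xhat = xhat, invstd = invstd, dim_in = d, training = training))
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$dim_in
  dym <- dy
  dim(dym) <- c(d[1], length(dy) %/% d[1])
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * gamma
  if (cache$training) {
    dxm <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
      cache$invstd
  } else {
    dxm <- dxhat * cache$invstd
  }
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

avgpool2_forward <- function(x) {
  d <- dim(x)
  h2 <- d[2] %/% 2L
  w2 <- d[3] %/% 2L
  a <- 2L * seq_len(h2) - 1L
  b <- 2L * seq_len(w2) - 1L
  out <- (x[, a, b, , drop = FALSE] + x[, a + 1L, b, , drop = FALSE] +
    x[, a, b + 1L, , drop = FALSE] + x[, a + 1L, b + 1L, , drop = FALSE]) / 4
  list(out = out, cache = d)
}

avgpool2_backward <- function(dy, cache) {
  d <- cache
  h2 <- dim(dy)[2]
  w2 <- dim(dy)[3]
  a <- 2L * seq_len(h2) - 1L
  b <- 2L * seq_len(w2) - 1L
  dx <- array(0, dim = d)
  q <- dy / 4
  dx[, a, b, ] <- q
  dx[, a + 1L, b, ] <- q
  dx[, a, b + 1L, ] <- q
  dx[, a + 1L, b + 1L, ] <- q
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  xr <- x
  dim(xr) <- c(d[1], d[2] * d[3], d[4])
  out <- apply(xr, 3L, rowMeans)
  dim(out) <- c(d[1], d[4])
  list(out = out, cache = d)
}

gap_backward <- function(dy, cache) {
  d <- cache
  per <- d[2] * d[3]
  dx <- dy[, rep(seq_len(d[4]), each = per), drop = FALSE] / per
  dim(dx) <- d
  dx
}

dense_forward <- function(x, w, b) {
  list(out = w %*% x + b, cache = x)
}

dense_backward <- function(dy, w, cache) {
  list(dx = crossprod(w, dy), dw = tcrossprod(dy, cache), db = rowSums(dy))
}

# Stable BCE on logits; `weights` are per-sample; the loss is the weighted
# mean. Returns the loss, dL/dlogit and the probabilities.
bce_with_logits <- function(logits, y, weights = NULL) {
  z <- as.numeric(logits)
  if (is.null(weights)) weights <- rep(1, length(z))
  wsum <- sum(weights)
  loss <- sum(weights * (pmax(z, 0) - y * z + log1p(exp(-abs(z))))) / wsum
  p <- 1 / (1 + exp(-z))
  dz <- weights * (p - y) / wsum
  list(loss = loss, dlogits = matrix(dz, nrow = 1L), prob = p)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
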