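# Low-level differentiable layers.  All layers take/return H x W x C arrays
# (single sample) or N x D token matrices, and come in _fwd / _bwd pairs:
# _fwd returns list(out = ..., <cache fields>), _bwd consumes the upstream
# gradient plus the cache and returns input/parameter gradients.  Caches hold
# layer inputs, never im2col expansions, so memory stays proportional to the
# activations; the patch matrices are recomputed in the backward pass.

# Cap on elements of one im2col strip (~160 MB of doubles at 2e7).
.IM2COL_MAX <- 2e7

pad_zeros <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L]))
  out[pad + seq_len(d[1L]), pad + seq_len(d[2L]), ] <- x
  out
}

# 2D convolution, stride 1, 'same' output size; pad = dilation for 3x3
# kernels and 0 for 1x1.  W is a (C*k*k) x Cout matrix in the layout of
# im2col_strip; b is length Cout.
conv2d_fwd <- function(x, W, b, k, dil = 1L) {
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; C <- d[3L]
  pad <- if (k == 1L) 0L else as.integer(dil)
  xp <- pad_zeros(x, pad)
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  Cout <- ncol(W)
  out <- matrix(0, H * Wd, Cout)
  nc <- max(1L, min(Wd, as.integer(.IM2COL_MAX %/% (H * nrow(W)))))
  c0 <- 0L
  while (c0 < Wd) {
    n <- min(nc, Wd - c0)
    cols <- im2col_strip(xp, Hp, Wp, C, k, dil, H, Wd, c0, n)
    out[c0 * H + seq_len(n * H), ] <- cols %*% W
    c0 <- c0 + n
  }
  out <- sweep(out, 2L, b, `+`)
  list(out = array(out, c(H, Wd, Cout)), x = x, k = k, dil = dil)
}

conv2d_bwd <- function(dout, cache, W) {
  x <- cache$x; k <- cache$k; dil <- cache$dil
  d <- dim(x)
  H <- d[1L]; Wd <- d[2L]; C <- d[3L]
  pad <- if (k == 1L) 0L else as.integer(dil)
  xp <- pad_zeros(x, pad)
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  Cout <- ncol(W)
  dom <- matrix(dout, H * Wd, Cout)
  dW <- matrix(0, nrow(W), Cout)
  gpad <- numeric(Hp * Wp * C)
  nc <- max(1L, min(Wd, as.integer(.IM2COL_MAX %/% (H * nrow(W)))))
  c0 <- 0L
  while (c0 < Wd) {
    n <- min(nc, Wd - c0)
    rows <- c0 * H + seq_len(n * H)
    cols <- im2col_strip(xp, Hp, Wp, C, k, dil, H, Wd, c0, n)
    dW <- dW + crossprod(cols, dom[rows, , drop = FALSE])
    dcols <- dom[rows, , drop = FALSE] %*% t(W)
    col2im_strip(gpad, dcols, Hp, Wp, C, k, dil, H, Wd, c0, n)
    c0 <- c0 + n
  }
  gpad <- array(gpad, c(Hp, Wp, C))
  dx <- if (pad == 0L) gpad else
    gpad[pad + seq_len(H), pad + seq_len(Wd), , drop = FALSE]
  list(dx = dx, dW = dW, db = colSums(dom))
}

# 2x2 pooling, stride 2 ---------------------------------------------------

pool_subs <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2L], 2L); j2 <- j1 + 1L
  list(x[i1, j1, , drop = FALSE], x[i2, j1, , drop = FALSE],
       x[i1, j2, , drop = FALSE], x[i2, j2, , drop = FALSE])
}

avgpool2 <- function(x) {
  s <- pool_subs(x)
  (s[[1L]] + s[[2L]] + s[[3L]] + s[[4L]]) / 4
}

maxpool2_fwd <- function(x) {
  s <- pool_subs(x)
  m <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  wh <- array(0L, dim(m))
  for (t in 1:4) {
    sel <- wh == 0L & s[[t]] == m
    wh[sel] <- t
  }
  list(out = m, which = wh, in_dim = dim(x))
}

maxpool2_bwd <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  i1 <- seq(1L, d[1L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2L], 2L); j2 <- j1 + 1L
  offs <- list(list(i1, j1), list(i2, j1), list(i1, j2), list(i2, j2))
  for (t in 1:4) {
    g <- dout
    g[cache$which != t] <- 0
    dx[offs[[t]][[1L]], offs[[t]][[2L]], ] <- g
  }
  dx
}

# Bilinear 2x upsampling --------------------------------------------------
# Built from an explicit (2n x n) interpolation matrix applied along each
# spatial axis; the backward pass is the transpose.  Output pixel i (0-based)
# samples source coordinate (i + 0.5)/2 - 0.5 with edge clamping.

make_upmat <- function(n) {
  cache_get(paste0("up", n), function() {
    M <- matrix(0, 2L * n, n)
    for (i in 0:(2L * n - 1L)) {
      src <- (i + 0.5) / 2 - 0.5
      i0 <- floor(src)
      w <- src - i0
      j0 <- min(max(i0, 0), n - 1)
      j1 <- min(max(i0 + 1, 0), n - 1)
      M[i + 1L, j0 + 1L] <- M[i + 1L, j0 + 1L] + (1 - w)
      M[i + 1L, j1 + 1L] <- M[i + 1L, j1 + 1L] + w
    }
    M
  })
}

up2_apply <- function(x, transpose = FALSE) {
  d <- dim(x)
  A <- make_upmat(if (transpose) d[1L] %/% 2L else d[1L])
  if (transpose) A <- t(A)
  y <- A %*% matrix(x, d[1L], d[2L] * d[3L])
  H2 <- nrow(A)
  y <- aperm(array(y, c(H2, d[2L], d[3L])), c(2L, 1L, 3L))
  B <- make_upmat(if (transpose) d[2L] %/% 2L else d[2L])
  if (transpose) B <- t(B)
  z <- B %*% matrix(y, d[2L], H2 * d[3L])
  aperm(array(z, c(nrow(B), H2, d[3L])), c(2L, 1L, 3L))
}

upsample2_fwd <- function(x) list(out = up2_apply(x, FALSE))
upsample2_bwd <- function(dout) up2_apply(dout, TRUE)

# Pointwise activations ---------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dout, cache) dout * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

gelu_fwd <- function(x) list(out = x * pnorm(x), x = x)
gelu_bwd <- function(dout, cache) {
  x <- cache$x
  dout * (pnorm(x) + x * dnorm(x))
}

# Token-matrix layers -----------------------------------------------------

linear_fwd <- function(x, W, b) {
  list(out = sweep(x %*% W, 2L, b, `+`), x = x)
}

linear_bwd <- function(dout, cache, W) {
  list(dx = dout %*% t(W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

# LayerNorm over the feature axis of an N x D matrix, learnable gain g and
# bias b of length D.
layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`)
  list(out = out, xhat = xhat, istd = istd)
}

layernorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$istd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

# Scaled dot-product self-attention (optionally multi-head by slicing the
# projected q/k/v into contiguous column blocks; no output projection).
attention_fwd <- function(x, Wq, Wk, Wv, n_heads = 1L) {
  q <- x %*% Wq
  k <- x %*% Wk
  v <- x %*% Wv
  D <- ncol(q)
  hs <- D %/% n_heads
  y <- matrix(0, nrow(x), D)
  alphas <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    ix <- (h - 1L) * hs + seq_len(hs)
    s <- tcrossprod(q[, ix, drop = FALSE], k[, ix, drop = FALSE]) / sqrt(hs)
    a <- softmax_rows(s)
    alphas[[h]] <- a
    y[, ix] <- a %*% v[, ix, drop = FALSE]
  }
  list(out = y, alphas = alphas, q = q, k = k, v = v, x = x,
       n_heads = n_heads)
}

attention_bwd <- function(dout, cache, Wq, Wk, Wv) {
  q <- cache$q; k <- cache$k; v <- cache$v; x <- cache$x
  n_heads <- cache$n_heads
  D <- ncol(q)
  hs <- D %/% n_heads
  dq <- matrix(0, nrow(q), D)
  dk <- dq; dv <- dq
  for (h in seq_len(n_heads)) {
    ix <- (h - 1L) * hs + seq_len(hs)
    a <- cache$alphas[[h]]
    dy <- dout[, ix, drop = FALSE]
    dv[, ix] <- crossprod(a, dy)
    da <- tcrossprod(dy, v[, ix, drop = FALSE])
    ds <- a * (da - rowSums(a * da))
    dq[, ix] <- ds %*% k[, ix, drop = FALSE] / sqrt(hs)
    dk[, ix] <- crossprod(ds, q[, ix, drop = FALSE]) / sqrt(hs)
  }
  list(dx = dq %*% t(Wq) + dk %*% t(Wk) + dv %*% t(Wv),
       dWq = crossprod(x, dq), dWk = crossprod(x, dk), dWv = crossprod(x, dv))
}

# Weight initialisation ---------------------------------------------------

init_he <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

init_glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}
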