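# Unit checks of the differentiable building blocks against brute-force
# oracles and finite differences.

brute_conv <- function(x, W, b, k, dil) {
  # direct loop convolution, same layout as conv2d_fwd
  d <- dim(x)
  Cout <- ncol(W)
  pad <- if (k == 1L) 0L else dil
  out <- array(0, c(d[1L], d[2L], Cout))
  for (o in seq_len(Cout)) {
    for (r in seq_len(d[1L])) for (cc in seq_len(d[2L])) {
      acc <- b[o]
      for (ch in seq_len(d[3L])) for (kc in 0:(k - 1L)) for (kr in 0:(k - 1L)) {
        rr <- r + (kr - (k - 1L) / 2) * dil
        ccc <- cc + (kc - (k - 1L) / 2) * dil
        if (rr >= 1 && rr <= d[1L] && ccc >= 1 && ccc <= d[2L]) {
          wcol <- (ch - 1L) * k * k + kc * k + kr + 1L
          acc <- acc + x[rr, ccc, ch] * W[wcol, o]
        }
      }
      out[r, cc, o] <- acc
    }
  }
  out
}

test_that("dilated convolution matches a direct-loop oracle", {
  set.seed(1)
  x <- array(rnorm(10 * 12 * 2), c(10, 12, 2))
  for (dil in c(1L, 2L, 3L, 5L)) {
    W <- matrix(rnorm(2 * 9 * 3), 18, 3)
    b <- rnorm(3)
    got <- dbmsc:::conv2d_fwd(x, W, b, 3L, dil)$out
    expect_rel_equal(got, brute_conv(x, W, b, 3L, dil), 1e-10)
  }
  W1 <- matrix(rnorm(2 * 4), 2, 4)
  got1 <- dbmsc:::conv2d_fwd(x, W1, rnorm(4) * 0, 1L, 1L)$out
  expect_rel_equal(got1, brute_conv(x, W1, numeric(4), 1L, 1L), 1e-10)
})

test_that("an impulse through a dilation-5 branch responds only at +/-5 offsets", {
  x <- array(0, c(16, 16, 1))
  x[8, 8, 1] <- 1
  W <- matrix(1, 9, 1)  # all nine taps active
  out <- dbmsc:::conv2d_fwd(x, W, 0, 3L, 5L)$out[, , 1]
  nz <- which(out != 0, arr.ind = TRUE)
  expect_setequal(unique(nz[, 1]) - 8, c(-5, 0, 5))
  expect_setequal(unique(nz[, 2]) - 8, c(-5, 0, 5))
  expect_equal(nrow(nz), 9L)
})

test_that("convolution gradients agree with finite differences", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  W <- matrix(rnorm(18 * 2), 18, 2)
  b <- rnorm(2)
  tgt <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  loss <- function(x, W, b) sum(dbmsc:::conv2d_fwd(x, W, b, 3L, 2L)$out * tgt)
  fw <- dbmsc:::conv2d_fwd(x, W, b, 3L, 2L)
  bw <- dbmsc:::conv2d_bwd(tgt, fw, W)
  eps <- 1e-6
  for (probe in 1:5) {
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_rel_equal(bw$dx[i], (loss(xp, W, b) - loss(xm, W, b)) / (2 * eps), 1e-5)
    j <- sample(length(W), 1)
    Wp <- W; Wp[j] <- Wp[j] + eps
    Wm <- W; Wm[j] <- Wm[j] - eps
    expect_rel_equal(bw$dW[j], (loss(x, Wp, b) - loss(x, Wm, b)) / (2 * eps), 1e-5)
  }
  expect_rel_equal(bw$db, apply(tgt, 3, sum), 1e-10)
})

test_that("im2col and col2im are adjoint", {
  set.seed(3)
  x <- array(rnorm(6 * 7 * 2), c(6, 7, 2))
  xp <- dbmsc:::pad_zeros(x, 2L)
  cols <- dbmsc:::im2col_strip(xp, 10L, 11L, 2L, 3L, 2L, 6L, 7L, 0L, 7L)
  Cm <- matrix(rnorm(length(cols)), nrow(cols), ncol(cols))
  g <- numeric(length(xp))
  dbmsc:::col2im_strip(g, Cm, 10L, 11L, 2L, 3L, 2L, 6L, 7L, 0L, 7L)
  expect_equal(sum(cols * Cm), sum(xp * array(g, dim(xp))))
})

test_that("pooling layers implement 2x2 windows with correct routing", {
  x <- array(0, c(4, 4, 1))
  x[, , 1] <- matrix(c(1, 5, 2, 0,
                       3, 4, 8, 1,
                       0, 2, 6, 7,
                       9, 1, 3, 2), 4, 4, byrow = TRUE)
  expect_equal(dbmsc:::avgpool2(x)[, , 1],
               matrix(c(13, 11, 12, 18) / 4, 2, 2, byrow = TRUE))
  mp <- dbmsc:::maxpool2_fwd(x)
  expect_equal(mp$out[, , 1], matrix(c(5, 8, 9, 7), 2, 2, byrow = TRUE))
  dx <- dbmsc:::maxpool2_bwd(array(c(10, 20, 30, 40), c(2, 2, 1)), mp)
  expect_equal(sum(dx != 0), 4L)          # gradient only at the argmax pixels
  expect_equal(dx[1, 2, 1], 10)           # max 5 at (1,2)
  expect_equal(dx[4, 1, 1], 20)           # max 9 at (4,1)
  expect_equal(sum(dx), 100)
})

test_that("bilinear 2x upsampling matches direct interpolation and transposes", {
  set.seed(4)
  x <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  up <- dbmsc:::upsample2_fwd(x)$out
  expect_equal(dim(up), c(8L, 12L, 2L))
  # direct oracle: out[i] = (1-w) x[j0] + w x[j1], src = (i+0.5)/2 - 0.5
  interp1 <- function(v) {
    n <- length(v)
    sapply(0:(2 * n - 1), function(i) {
      src <- (i + 0.5) / 2 - 0.5
      j0 <- floor(src); w <- src - j0
      (1 - w) * v[min(max(j0, 0), n - 1) + 1] + w * v[min(max(j0 + 1, 0), n - 1) + 1]
    })
  }
  ref <- apply(x, c(2, 3), interp1)           # rows first
  ref <- aperm(apply(ref, c(1, 3), interp1), c(2, 1, 3))  # then columns
  expect_rel_equal(up, ref, 1e-12)
  # adjointness <Ux, y> = <x, U'y>
  y <- array(rnorm(8 * 12 * 2), c(8, 12, 2))
  expect_equal(sum(up * y), sum(x * dbmsc:::upsample2_bwd(y)))
})

test_that("layernorm and attention gradients agree with finite differences", {
  set.seed(5)
  x <- matrix(rnorm(12), 3, 4)
  g <- runif(4, 0.5, 1.5); b <- rnorm(4)
  tgt <- matrix(rnorm(12), 3, 4)
  fw <- dbmsc:::layernorm_fwd(x, g, b)
  bw <- dbmsc:::layernorm_bwd(tgt, fw, g)
  eps <- 1e-6
  num <- function(f) (f(eps) - f(-eps)) / (2 * eps)
  for (i in c(1, 7, 12)) {
    expect_rel_equal(bw$dx[i], num(function(e) {
      xp <- x; xp[i] <- xp[i] + e
      sum(dbmsc:::layernorm_fwd(xp, g, b)$out * tgt)
    }), 1e-5)
  }
  Wq <- matrix(rnorm(16), 4, 4); Wk <- matrix(rnorm(16), 4, 4)
  Wv <- matrix(rnorm(16), 4, 4)
  fa <- dbmsc:::attention_fwd(x, Wq, Wk, Wv)
  ba <- dbmsc:::attention_bwd(tgt, fa, Wq, Wk, Wv)
  for (i in c(2, 9)) {
    expect_rel_equal(ba$dx[i], num(function(e) {
      xp <- x; xp[i] <- xp[i] + e
      sum(dbmsc:::attention_fwd(xp, Wq, Wk, Wv)$out * tgt)
    }), 1e-4)
    expect_rel_equal(ba$dWq[i], num(function(e) {
      Wp <- Wq; Wp[i] <- Wp[i] + e
      sum(dbmsc:::attention_fwd(x, Wp, Wk, Wv)$out * tgt)
    }), 1e-4)
  }
})
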