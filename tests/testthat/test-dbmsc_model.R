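test_that("channel attention reproduces the constant-map hand example", {
  # two constant channels at (1, 0); identity MLP (r = 1): avg = max per
  # channel, so the gate is sigmoid(2 * v): (0.8808, 0.5)
  x <- array(0, c(3, 3, 2))
  x[, , 1] <- 1
  par <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  ca <- channel_attention(x, params = par)
  expect_equal(round(ca$scales, 4), c(0.8808, 0.5))
  expect_equal(round(ca$out[1, 1, 1], 4), 0.8808)
  expect_true(all(ca$out[, , 2] == 0))
})

test_that("channel attention gates within (0,1) and preserves zeros", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  ca <- channel_attention(x, reduction = 2L, seed = 2L)
  expect_true(all(ca$scales > 0 & ca$scales < 1))
  expect_true(all(abs(ca$out) <= abs(x)))  # per-element gating bound
  expect_equal(dim(ca$out), dim(x))
  z <- channel_attention(array(0, c(4, 4, 3)), reduction = 2L, seed = 3L)
  expect_true(all(z$out == 0))
  expect_warning(channel_attention(x[, , 1:2, drop = FALSE], reduction = 8L),
                 "clamping")
})

test_that("channel attention gradients agree with finite differences", {
  set.seed(4)
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  par <- with(list(), dbmsc:::init_cam(4L, 2L))
  tgt <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  fw <- dbmsc:::cam_fwd(x, par)
  bw <- dbmsc:::cam_bwd(tgt, fw, par)
  eps <- 1e-6
  for (i in c(1, 40, 99)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (sum(dbmsc:::cam_fwd(xp, par)$out * tgt) -
            sum(dbmsc:::cam_fwd(xm, par)$out * tgt)) / (2 * eps)
    expect_rel_equal(bw$dx[i], num, 1e-5)
  }
  for (j in 1:2) {
    pp <- par; pp$W1[j] <- pp$W1[j] + eps
    pm <- par; pm$W1[j] <- pm$W1[j] - eps
    num <- (sum(dbmsc:::cam_fwd(x, pp)$out * tgt) -
            sum(dbmsc:::cam_fwd(x, pm)$out * tgt)) / (2 * eps)
    expect_rel_equal(bw$grads$W1[j], num, 1e-5)
  }
})

test_that("binary cross-entropy matches closed forms", {
  expect_equal(bce_loss(matrix(0.5, 4, 4), matrix(rbinom(16, 1, 0.5), 4, 4)),
               log(2))
  expect_equal(round(bce_loss(c(0.8, 0.4), c(1, 0)), 4), 0.3670)
  expect_equal(bce_loss(c(0.8, 0.4), c(1, 0)), -(log(0.8) + log(0.6)) / 2)
  y <- matrix(rbinom(16, 1, 0.4), 4, 4)
  expect_lt(bce_loss(y, y), 1.1e-7)  # perfect prediction, post-clamp
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("decoder output is a full-resolution single-channel map", {
  cfg <- tiny_cfg()
  m <- suppressWarnings(build_model(cfg, seed = 5L))
  s <- rand_tile(6L, 16L)
  fw <- dbmsc:::model_fwd(m, s$rgb, s$ndvi, keep_cache = TRUE)
  expect_equal(dim(fw$logits), c(16L, 16L, 1L))
  expect_equal(dim(fw$prob), c(16L, 16L))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # P-series doubles in size towards full resolution (P1 last, full size)
  expect_equal(fw$dc$p_sizes, c(16L, 8L))
  # Q5 concatenates both branch tops
  q5 <- dim(fw$ea$features[[3]])[3] + dim(fw$eb$features[[3]])[3]
  expect_equal(q5, 18L)
})

test_that("forward is deterministic and the branches are asymmetric", {
  cfg <- tiny_cfg()
  m <- suppressWarnings(build_model(cfg, seed = 7L))
  set.seed(8)
  a <- matrix(runif(256), 16, 16)
  b <- matrix(runif(256), 16, 16)
  rep3 <- function(v) array(rep(v, 3), c(16, 16, 3))
  p1 <- forward_pass(m, rep3(a), b)
  expect_identical(p1, forward_pass(m, rep3(a), b))  # bit-identical repeat
  p2 <- forward_pass(m, rep3(b), a)
  expect_false(isTRUE(all.equal(p1, p2)))  # swapping the branches matters
})

test_that("model rebuilds reproducibly and counts parameters stably", {
  cfg <- tiny_cfg()
  m1 <- suppressWarnings(build_model(cfg, seed = 9L))
  m2 <- suppressWarnings(build_model(cfg, seed = 9L))
  expect_identical(count_params(m1), count_params(m2))
  expect_identical(m1$params, m2$params)
  m3 <- suppressWarnings(build_model(cfg, seed = 10L))
  expect_false(identical(m1$params, m3$params))
})

test_that("whole-network gradients agree with finite differences", {
  set.seed(11)
  cfg <- tiny_cfg()
  m <- suppressWarnings(build_model(cfg, seed = 12L))
  s <- rand_tile(13L, 16L)
  loss_of <- function(params) {
    mm <- m; mm$params <- params
    bce_loss(dbmsc:::model_fwd(mm, s$rgb, s$ndvi)$prob, s$mask)
  }
  fw <- dbmsc:::model_fwd(m, s$rgb, s$ndvi, keep_cache = TRUE)
  ld <- dbmsc:::loss_and_dlogits(fw, s$mask)
  g <- dbmsc:::model_bwd(m, fw, ld$dlogits)
  fl_g <- dbmsc:::par_flatten(g)
  fl_p <- dbmsc:::par_flatten(m$params)
  expect_identical(names(fl_g), names(fl_p))
  eps <- 1e-5
  # probe one random scalar in a spread of tensors across all module groups
  probe <- grep("(enc_rgb\\.1|enc_ndvi\\.2|enc_rgb\\.3|dec)", names(fl_p),
                value = TRUE)
  for (nm in probe) {
    j <- sample(length(fl_p[[nm]]), 1L)
    num <- (loss_of(perturb_param(m$params, nm, j, eps)) -
            loss_of(perturb_param(m$params, nm, j, -eps))) / (2 * eps)
    ana <- fl_g[[nm]][j]
    expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 1e-3)
  }
})

test_that("checkpoints round-trip and validate their configuration", {
  cfg <- tiny_cfg()
  m <- suppressWarnings(build_model(cfg, seed = 14L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  s <- rand_tile(15L, 16L)
  expect_identical(forward_pass(m, s$rgb, s$ndvi),
                   forward_pass(m2, s$rgb, s$ndvi))
  # corrupt the weights: shapes no longer match the embedded config
  bad <- readRDS(path)
  bad$params$dec$head$W <- bad$params$dec$head$W[1:10, , drop = FALSE]
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "incompatible")
})
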