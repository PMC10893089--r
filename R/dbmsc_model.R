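# Full double-branch network: two MSC encoder branches (RGB and NDVI), a
# channel-attention-gated decoder that upsamples and re-concatenates the two
# pyramids stage by stage, and a single-channel sigmoid head trained with
# binary cross-entropy.

# Channel attention -------------------------------------------------------

init_cam <- function(C, r) {
  h <- max(1L, C %/% r)
  list(W1 = init_he(C, h), b1 = numeric(h),
       W2 = init_glorot(h, C), b2 = numeric(C))
}

cam_mlp <- function(v, par) {
  h1 <- v %*% par$W1 + par$b1
  hr <- pmax(h1, 0)
  list(out = drop(hr %*% par$W2) + par$b2, hr = hr, mask = h1 > 0, v = v)
}

cam_fwd <- function(x, par) {
  d <- dim(x)
  HW <- d[1L] * d[2L]
  xm <- matrix(x, HW, d[3L])
  av <- colMeans(xm)
  mxi <- max.col(t(xm), ties.method = "first")  # argmax pixel per channel
  mx <- xm[cbind(mxi, seq_len(d[3L]))]
  pa <- cam_mlp(matrix(av, 1L), par)
  pm <- cam_mlp(matrix(mx, 1L), par)
  s <- sigmoid(pa$out + pm$out)
  out <- xm * rep(s, each = HW)
  list(out = array(out, d), s = s, pa = pa, pm = pm, mxi = mxi, x = x)
}

cam_bwd <- function(dout, cache, par) {
  d <- dim(cache$x)
  HW <- d[1L] * d[2L]
  C <- d[3L]
  dom <- matrix(dout, HW, C)
  xm <- matrix(cache$x, HW, C)
  s <- cache$s
  dx <- dom * rep(s, each = HW)
  dsv <- colSums(dom * xm)                      # dL/ds per channel
  dz <- dsv * s * (1 - s)                       # through the sigmoid
  mlp_bwd <- function(pc, dz) {
    dW2 <- crossprod(pc$hr, matrix(dz, 1L))
    db2 <- dz
    dhr <- matrix(dz, 1L) %*% t(par$W2)
    dh1 <- dhr * pc$mask
    dW1 <- crossprod(pc$v, dh1)
    db1 <- drop(dh1)
    list(dv = drop(dh1 %*% t(par$W1)), dW1 = dW1, db1 = db1,
         dW2 = dW2, db2 = db2)
  }
  ba <- mlp_bwd(cache$pa, dz)
  bm <- mlp_bwd(cache$pm, dz)
  # avg-pool path spreads uniformly; max-pool path goes to the argmax pixel
  dx <- dx + matrix(rep(ba$dv / HW, each = HW), HW, C)
  dx[cbind(cache$mxi, seq_len(C))] <- dx[cbind(cache$mxi, seq_len(C))] + bm$dv
  list(dx = array(dx, d),
       grads = list(W1 = ba$dW1 + bm$dW1, b1 = ba$db1 + bm$db1,
                    W2 = ba$dW2 + bm$dW2, b2 = ba$db2 + bm$db2))
}

#' Channel attention gate
#'
#' Squeezes the input feature map to per-channel average- and max-pooled
#' vectors, passes both through one shared two-layer ReLU MLP (hidden width
#' `C / reduction`, clamped to at least 1), sums the outputs, applies a
#' sigmoid to obtain per-channel scales in (0, 1), and rescales the input
#' channels.  Output magnitude never exceeds input magnitude.
#'
#' @param feature `H x W x C` feature map.
#' @param params Optional parameters (`W1`, `b1`, `W2`, `b2`); fresh ones are
#'   drawn when `NULL`.
#' @param reduction Channel reduction ratio `r` (default 8).
#' @param seed Seed for fresh initialisation.
#' @return List with `out` (same shape as input), `scales` (length-`C`
#'   vector in (0, 1)), and `params`.
#' @export
channel_attention <- function(feature, params = NULL, reduction = 8L,
                              seed = 1L) {
  feature <- as_hwc(feature)
  C <- dim(feature)[3L]
  if (is.null(params)) {
    if (C < reduction) {
      warning("channel count ", C, " below reduction ", reduction,
              "; clamping the attention MLP hidden width to 1")
    }
    params <- with_seed(seed, init_cam(C, reduction))
  }
  fw <- cam_fwd(feature, params)
  list(out = fw$out, scales = drop(fw$s), params = params)
}

# Decoder -----------------------------------------------------------------

init_decoder <- function(cfg) {
  n <- cfg$n_stages
  wch <- 4L * cfg$msc$widths + 1L      # encoder stage channels
  qc <- integer(n)                     # channels of Q_i
  qc[n] <- 2L * wch[n]
  blocks <- vector("list", n - 1L)
  for (i in (n - 1L):1L) {
    dw <- cfg$decoder_widths[i]
    if (dw < cfg$cam_reduction) {
      warning("decoder stage ", i, ": width ", dw, " below cam_reduction ",
              cfg$cam_reduction, "; clamping the attention hidden width to 1")
    }
    blocks[[i]] <- list(conv_W = init_he(qc[i + 1L] * 9L, dw),
                        conv_b = numeric(dw),
                        cam = init_cam(dw, cfg$cam_reduction))
    qc[i] <- 2L * wch[i] + dw
  }
  list(blocks = blocks, head = list(W = init_he(qc[1L] * 9L, 1L),
                                    b = numeric(1L)))
}

decode_fwd <- function(fa, fb, dec_par, cfg) {
  n <- cfg$n_stages
  if (length(fa) != n || length(fb) != n) {
    stop("config error: pyramid depth must equal n_stages = ", n)
  }
  caches <- vector("list", n - 1L)
  q <- concat_ch(fa[[n]], fb[[n]])
  p_sizes <- integer(n - 1L)
  for (i in (n - 1L):1L) {
    up <- upsample2_fwd(q)
    cv <- conv2d_fwd(up$out, dec_par$blocks[[i]]$conv_W,
                     dec_par$blocks[[i]]$conv_b, 3L, 1L)
    rl <- relu_fwd(cv$out)
    cm <- cam_fwd(rl$out, dec_par$blocks[[i]]$cam)
    caches[[i]] <- list(cv = cv, rl = rl, cm = cm,
                        ca = dim(fa[[i]])[3L], cp = dim(cm$out)[3L])
    p_sizes[i] <- dim(cm$out)[1L]
    q <- concat_ch(fa[[i]], cm$out, fb[[i]])
  }
  hd <- conv2d_fwd(q, dec_par$head$W, dec_par$head$b, 3L, 1L)
  list(out = hd$out, hd = hd, caches = caches, p_sizes = p_sizes)
}

decode_bwd <- function(dlogits, cache, dec_par, cfg) {
  n <- cfg$n_stages
  hb <- conv2d_bwd(dlogits, cache$hd, dec_par$head$W)
  dq <- hb$dx
  dfa <- vector("list", n)
  dfb <- vector("list", n)
  blocks_g <- vector("list", n - 1L)
  for (i in 1:(n - 1L)) {
    ci <- cache$caches[[i]]
    ca <- ci$ca; cp <- ci$cp
    dfa[[i]] <- take_ch(dq, seq_len(ca))
    dp <- take_ch(dq, ca + seq_len(cp))
    dfb[[i]] <- take_ch(dq, ca + cp + seq_len(dim(dq)[3L] - ca - cp))
    cb <- cam_bwd(dp, ci$cm, dec_par$blocks[[i]]$cam)
    drl <- relu_bwd(cb$dx, ci$rl)
    cvb <- conv2d_bwd(drl, ci$cv, dec_par$blocks[[i]]$conv_W)
    dq <- upsample2_bwd(cvb$dx)
    blocks_g[[i]] <- list(conv_W = cvb$dW, conv_b = cvb$db, cam = cb$grads)
  }
  cn <- dim(dq)[3L] %/% 2L
  dfa[[n]] <- take_ch(dq, seq_len(cn))
  dfb[[n]] <- take_ch(dq, cn + seq_len(cn))
  list(dfa = dfa, dfb = dfb,
       grads = list(blocks = blocks_g,
                    head = list(W = hb$dW, b = hb$db)))
}

# Model -------------------------------------------------------------------

#' Build a double-branch segmentation model
#'
#' Initialises all learnable parameters (variance-scaled convolutions and
#' projections, zero positional embeddings and biases) for the configured
#' architecture and verifies the channel arithmetic of every stage: the four
#' concatenated dilated branches must match the 1x1 branch (`4w` channels)
#' for their elementwise sum to be well formed.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the initialisation.
#' @return An object of class `dbmsc_model` with elements `config` and
#'   `params`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "dbmsc_config"))
  params <- with_seed(seed, list(
    enc_rgb = init_branch(cfg, 3L, cfg$tile_size),
    enc_ndvi = init_branch(cfg, 1L, cfg$tile_size),
    dec = NULL
  ))
  params$dec <- with_seed(seed + 1L, init_decoder(cfg))
  # channel arithmetic: concat(f1..f4) must equal f5 for the Eq-style sum
  for (br in c("enc_rgb", "enc_ndvi")) {
    for (i in seq_len(cfg$n_stages)) {
      loc <- params[[br]][[i]]$loc
      stopifnot(4L * ncol(loc$W1) == ncol(loc$W5))
    }
  }
  structure(list(config = cfg, params = params), class = "dbmsc_model")
}

#' @export
print.dbmsc_model <- function(x, ...) {
  cfg <- x$config
  cat("dbmsc_model: ", cfg$n_stages, " stages, tile ", cfg$tile_size,
      ", patch ", cfg$msc$patch_size, ", depth ", cfg$msc$depth,
      ", widths ", paste(cfg$msc$widths, collapse = "/"),
      ", ", format(count_params(x), big.mark = ","), " parameters\n",
      sep = "")
  invisible(x)
}

#' Count learnable parameters
#'
#' @param model A `dbmsc_model`.
#' @return Total number of scalar parameters.
#' @export
count_params <- function(model) par_count(model$params)

model_fwd <- function(model, rgb, ndvi, keep_cache = FALSE) {
  cfg <- model$config
  rgb <- as_hwc(rgb); ndvi <- as_hwc(ndvi)
  ea <- encode_fwd(rgb, model$params$enc_rgb, cfg)
  eb <- encode_fwd(ndvi, model$params$enc_ndvi, cfg)
  dc <- decode_fwd(ea$features, eb$features, model$params$dec, cfg)
  prob <- sigmoid(dc$out[, , 1L])
  out <- list(prob = prob, logits = dc$out)
  if (keep_cache) {
    out$ea <- ea; out$eb <- eb; out$dc <- dc
  }
  out
}

# Backward from d(loss)/d(logits); returns the full gradient tree.
model_bwd <- function(model, fw, dlogits) {
  cfg <- model$config
  db <- decode_bwd(dlogits, fw$dc, model$params$dec, cfg)
  ga <- encode_bwd(db$dfa, fw$ea, model$params$enc_rgb, cfg)
  gb <- encode_bwd(db$dfb, fw$eb, model$params$enc_ndvi, cfg)
  list(enc_rgb = ga, enc_ndvi = gb, dec = db$grads)
}

#' Forward pass of the full network
#'
#' Encodes the RGB tile and the NDVI tile in their separate branches,
#' decodes with channel-attention gating, and returns per-pixel street-tree
#' probabilities.  Deterministic given fixed weights.
#'
#' @param model A [build_model()] result.
#' @param rgb `H x W x 3` array in `[0, 1]`.
#' @param ndvi `H x W` matrix or `H x W x 1` array in `[-1, 1]`.
#' @return `H x W` matrix of probabilities in (0, 1).
#' @export
forward_pass <- function(model, rgb, ndvi) {
  model_fwd(model, rgb, ndvi)$prob
}

#' @export
predict.dbmsc_model <- function(object, rgb, ndvi,
                                type = c("prob", "mask"), ...) {
  type <- match.arg(type)
  p <- forward_pass(object, rgb, ndvi)
  if (type == "prob") p else (p >= object$config$threshold) * 1
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-y log(p) - (1 - y) log(1 - p)`, with predictions
#' clamped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param y_pred Probability map in (0, 1).
#' @param y_true Binary mask of the same shape.
#' @param eps Clamp constant (default 1e-7).
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(y_pred, y_true, eps = 1e-7) {
  if (!identical(dim(y_pred), dim(y_true)) &&
      length(y_pred) != length(y_true)) {
    stop("shape mismatch between y_pred and y_true")
  }
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

# Checkpoints -------------------------------------------------------------

#' Save or load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the weights together with the
#' embedded model configuration; loading validates that the stored weights
#' match the stored configuration's shapes.
#'
#' @param model A `dbmsc_model`.
#' @param path File path.
#' @return `load_checkpoint()` returns the `dbmsc_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dbmsc_model"))
  saveRDS(list(format = "dbmsc-checkpoint-1", config = model$config,
               params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "dbmsc-checkpoint-1")) {
    stop("'", path, "' is not a dbmsc checkpoint")
  }
  model <- structure(list(config = ck$config, params = ck$params),
                     class = "dbmsc_model")
  ref <- suppressWarnings(build_model(ck$config, seed = 1L))
  shapes <- function(p) par_map(p, function(x) dim(x) %||% length(x))
  if (!identical(shapes(ref$params), shapes(model$params))) {
    stop("checkpoint weights are incompatible with the embedded config")
  }
  model
}
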