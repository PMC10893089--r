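# MSC block: patch-transformer global path + 5-branch dilated-convolution
# local path, fused by channel concatenation.  Forward functions cache what
# the hand-written backward pass needs; parameter trees are created by the
# init_* helpers and mirrored exactly by the gradient trees.

DILATIONS <- c(1L, 2L, 3L, 5L)

# Linear index map from an H x W x C array to an N x (p^2 C) patch matrix.
# Token order is raster over the patch grid; within a patch, position
# d = ch * p^2 + dr * p + dc (0-based), so for C = 1 the d-th value sits at
# pixel (patch origin) + (d %/% p, d %% p) — the layout reshape_global
# inverts.
patch_index <- function(H, W, C, p) {
  cache_get(paste("pi", H, W, C, p), function() {
    npc <- W %/% p
    N <- (H %/% p) * npc
    t0 <- 0:(N - 1L)
    pr <- t0 %/% npc
    pc <- t0 %% npc
    j0 <- 0:(p * p * C - 1L)
    ch <- j0 %/% (p * p)
    rem <- j0 %% (p * p)
    dr <- rem %/% p
    dc <- rem %% p
    r <- outer(pr * p, dr, `+`)
    cl <- outer(pc * p, dc, `+`)
    idx <- r + cl * H + matrix(ch * H * W, N, length(j0), byrow = TRUE) + 1L
    storage.mode(idx) <- "integer"
    idx
  })
}

init_patch_embed <- function(p, C, D, H, W) {
  N <- (H %/% p) * (W %/% p)
  list(W = init_glorot(p * p * C, D),
       b = numeric(D),
       pos = matrix(0, N, D))  # zero-initialised, learnable
}

patch_embed_fwd <- function(img, par, p) {
  d <- dim(img)
  if (d[1L] %% p != 0L || d[2L] %% p != 0L) {
    stop("shape error: ", d[1L], "x", d[2L],
         " input is not divisible by patch_size ", p)
  }
  idx <- patch_index(d[1L], d[2L], d[3L], p)
  P <- matrix(img[idx], nrow(idx), ncol(idx))
  lin <- linear_fwd(P, par$W, par$b)
  list(out = lin$out + par$pos, lin = lin)
}

patch_embed_bwd <- function(dout, cache, par) {
  lb <- linear_bwd(dout, cache$lin, par$W)
  # no input gradient: the patch side always consumes pooled raw data
  list(grads = list(W = lb$dW, b = lb$db, pos = dout))
}

init_transformer_block <- function(D, mlp_ratio, n_heads) {
  Dh <- as.integer(round(mlp_ratio * D))
  list(Wq = init_glorot(D, D), Wk = init_glorot(D, D), Wv = init_glorot(D, D),
       ln1_g = rep(1, D), ln1_b = numeric(D),
       mlp_W1 = init_he(D, Dh), mlp_b1 = numeric(Dh),
       mlp_W2 = init_glorot(Dh, D), mlp_b2 = numeric(D),
       ln2_g = rep(1, D), ln2_b = numeric(D))
}

# Post-norm ordering: attention -> residual -> LayerNorm -> MLP -> residual
# -> LayerNorm.
transformer_block_fwd <- function(x, par, n_heads = 1L) {
  at <- attention_fwd(x, par$Wq, par$Wk, par$Wv, n_heads)
  h1 <- x + at$out
  ln1 <- layernorm_fwd(h1, par$ln1_g, par$ln1_b)
  l1 <- linear_fwd(ln1$out, par$mlp_W1, par$mlp_b1)
  g <- gelu_fwd(l1$out)
  l2 <- linear_fwd(g$out, par$mlp_W2, par$mlp_b2)
  h2 <- ln1$out + l2$out
  ln2 <- layernorm_fwd(h2, par$ln2_g, par$ln2_b)
  list(out = ln2$out, at = at, ln1 = ln1, l1 = l1, g = g, l2 = l2, ln2 = ln2)
}

transformer_block_bwd <- function(dout, cache, par) {
  b2 <- layernorm_bwd(dout, cache$ln2, par$ln2_g)
  dh2 <- b2$dx
  bl2 <- linear_bwd(dh2, cache$l2, par$mlp_W2)
  dg <- gelu_bwd(bl2$dx, cache$g)
  bl1 <- linear_bwd(dg, cache$l1, par$mlp_W1)
  dln1_out <- dh2 + bl1$dx
  b1 <- layernorm_bwd(dln1_out, cache$ln1, par$ln1_g)
  dh1 <- b1$dx
  ba <- attention_bwd(dh1, cache$at, par$Wq, par$Wk, par$Wv)
  dx <- dh1 + ba$dx
  list(dx = dx,
       grads = list(Wq = ba$dWq, Wk = ba$dWk, Wv = ba$dWv,
                    ln1_g = b1$dg, ln1_b = b1$db,
                    mlp_W1 = bl1$dW, mlp_b1 = bl1$db,
                    mlp_W2 = bl2$dW, mlp_b2 = bl2$db,
                    ln2_g = b2$dg, ln2_b = b2$db))
}

# Flat reshape of the token matrix back to image geometry: token t's D = p^2
# values fill its source-patch footprint in raster order, giving a
# single-channel map of exactly the stage input's size.
reshape_global_fwd <- function(tokens, H, W, p) {
  N <- nrow(tokens); D <- ncol(tokens)
  if (N * D != H * W) {
    stop("shape error: ", N, " tokens x ", D, " dims cannot fill a ",
         H, "x", W, " map (N*D != H*W; requires embed_dim = patch_size^2)")
  }
  idx <- patch_index(H, W, 1L, p)
  f0 <- numeric(H * W)
  f0[idx] <- tokens
  array(f0, c(H, W, 1L))
}

reshape_global_bwd <- function(df0, H, W, p, N, D) {
  idx <- patch_index(H, W, 1L, p)
  matrix(df0[idx], N, D)
}

init_dilated_local <- function(C_in, w) {
  par <- list()
  for (i in 1:4) {
    par[[paste0("W", i)]] <- init_he(C_in * 9L, w)
    par[[paste0("b", i)]] <- numeric(w)
  }
  par$W5 <- init_he(C_in, 4L * w)
  par$b5 <- numeric(4L * w)
  par
}

# Four parallel 3x3 convolutions with dilations 1, 2, 3, 5 (each w channels,
# 'same' padding) concatenated by channel, plus a 1x1 convolution to 4w
# channels added elementwise.
dilated_local_fwd <- function(x, par) {
  convs <- vector("list", 4L)
  for (i in 1:4) {
    convs[[i]] <- conv2d_fwd(x, par[[paste0("W", i)]], par[[paste0("b", i)]],
                             3L, DILATIONS[i])
  }
  c5 <- conv2d_fwd(x, par$W5, par$b5, 1L)
  cat4 <- concat_ch(convs[[1L]]$out, convs[[2L]]$out, convs[[3L]]$out,
                    convs[[4L]]$out)
  list(out = cat4 + c5$out, convs = convs, c5 = c5,
       f = lapply(convs, `[[`, "out"), f5 = c5$out,
       w = ncol(par$W1))
}

dilated_local_bwd <- function(dout, cache, par) {
  w <- cache$w
  grads <- list()
  b5 <- conv2d_bwd(dout, cache$c5, par$W5)
  dx <- b5$dx
  grads$W5 <- b5$dW; grads$b5 <- b5$db
  for (i in 1:4) {
    sl <- take_ch(dout, (i - 1L) * w + seq_len(w))
    bi <- conv2d_bwd(sl, cache$convs[[i]], par[[paste0("W", i)]])
    dx <- dx + bi$dx
    grads[[paste0("W", i)]] <- bi$dW
    grads[[paste0("b", i)]] <- bi$db
  }
  # reorder gradient fields to match the parameter tree exactly
  list(dx = dx, grads = grads[names(par)])
}

init_msc_stage <- function(cfg, C_context, C_prev, H, W) {
  msc <- cfg$msc
  stage_w <- attr(cfg, "stage_w")  # set by caller
  list(pe = init_patch_embed(msc$patch_size, C_context, msc$embed_dim, H, W),
       tf = lapply(seq_len(msc$depth), function(d)
         init_transformer_block(msc$embed_dim, msc$mlp_ratio, msc$n_heads)),
       loc = init_dilated_local(C_prev, stage_w))
}

msc_fwd <- function(context, prev, par, msc) {
  dctx <- dim(context)
  dprev <- dim(prev)
  if (!identical(dctx[1:2], dprev[1:2])) {
    stop("shape error: context input ", dctx[1L], "x", dctx[2L],
         " and previous feature ", dprev[1L], "x", dprev[2L],
         " differ spatially")
  }
  pe <- patch_embed_fwd(context, par$pe, msc$patch_size)
  toks <- pe$out
  tf_caches <- vector("list", length(par$tf))
  for (d in seq_along(par$tf)) {
    tf_caches[[d]] <- transformer_block_fwd(toks, par$tf[[d]], msc$n_heads)
    toks <- tf_caches[[d]]$out
  }
  f0 <- reshape_global_fwd(toks, dctx[1L], dctx[2L], msc$patch_size)
  loc <- dilated_local_fwd(prev, par$loc)
  list(out = concat_ch(loc$out, f0), pe = pe, tf = tf_caches, loc = loc,
       H = dctx[1L], W = dctx[2L], N = nrow(toks), D = ncol(toks),
       n_tokens = nrow(toks))
}

msc_bwd <- function(dout, cache, par, msc) {
  cw <- dim(dout)[3L] - 1L
  dloc <- take_ch(dout, seq_len(cw))
  df0 <- take_ch(dout, cw + 1L)
  lb <- dilated_local_bwd(dloc, cache$loc, par$loc)
  dtok <- reshape_global_bwd(df0, cache$H, cache$W, msc$patch_size,
                             cache$N, cache$D)
  tf_grads <- vector("list", length(par$tf))
  for (d in rev(seq_along(par$tf))) {
    tb <- transformer_block_bwd(dtok, cache$tf[[d]], par$tf[[d]])
    dtok <- tb$dx
    tf_grads[[d]] <- tb$grads
  }
  pe <- patch_embed_bwd(dtok, cache$pe, par$pe)
  list(dprev = lb$dx,
       grads = list(pe = pe$grads, tf = tf_grads, loc = lb$grads))
}

init_branch <- function(cfg, C_in, tile) {
  msc <- cfg$msc
  stages <- vector("list", cfg$n_stages)
  for (i in seq_len(cfg$n_stages)) {
    H <- tile %/% 2L^(i - 1L)
    C_prev <- if (i == 1L) C_in else 4L * msc$widths[i - 1L] + 1L
    a <- cfg
    attr(a, "stage_w") <- msc$widths[i]
    stages[[i]] <- init_msc_stage(a, C_in, C_prev, H, H)
  }
  stages
}

encode_fwd <- function(x, branch_par, cfg) {
  n <- cfg$n_stages
  A <- vector("list", n)
  A[[1L]] <- x
  for (i in 2:n) A[[i]] <- avgpool2(A[[i - 1L]])
  FA <- vector("list", n)
  caches <- vector("list", n)
  pools <- vector("list", n)
  m1 <- msc_fwd(A[[1L]], A[[1L]], branch_par[[1L]], cfg$msc)
  FA[[1L]] <- m1$out
  caches[[1L]] <- m1
  for (i in 2:n) {
    mp <- maxpool2_fwd(FA[[i - 1L]])
    pools[[i]] <- mp
    mi <- msc_fwd(A[[i]], mp$out, branch_par[[i]], cfg$msc)
    FA[[i]] <- mi$out
    caches[[i]] <- mi
  }
  list(features = FA, caches = caches, pools = pools,
       sizes = vapply(A, function(a) dim(a)[1L], integer(1)),
       n_tokens = vapply(caches, `[[`, integer(1), "n_tokens"))
}

encode_bwd <- function(dFA, enc_cache, branch_par, cfg) {
  n <- cfg$n_stages
  grads <- vector("list", n)
  for (i in n:1) {
    mb <- msc_bwd(dFA[[i]], enc_cache$caches[[i]], branch_par[[i]], cfg$msc)
    grads[[i]] <- mb$grads
    if (i > 1L) {
      dFA[[i - 1L]] <- dFA[[i - 1L]] +
        maxpool2_bwd(mb$dprev, enc_cache$pools[[i]])
    }
  }
  grads
}

# Exported, documented surfaces -------------------------------------------

#' Patch embedding
#'
#' Cuts an image into non-overlapping `p x p` patches, flattens each and
#' applies a learnable linear projection to `embed_dim`-dimensional tokens;
#' a learnable positional embedding (initialised to zeros) is added.
#'
#' @param image `H x W x C` array (or `H x W` matrix), `H`, `W` divisible by
#'   `patch_size`.
#' @param patch_size Patch side `p`.
#' @param embed_dim Token width `D`.
#' @param params Optional parameter list from a previous call (fields `W`,
#'   `b`, `pos`); fresh parameters are initialised when `NULL`.
#' @param seed Seed for fresh initialisation.
#' @return List with `tokens` (`N x D`), `n_tokens`, and `params`.
#' @export
patch_embed <- function(image, patch_size, embed_dim = patch_size^2,
                        params = NULL, seed = 1L) {
  image <- as_hwc(image)
  d <- dim(image)
  if (is.null(params)) {
    params <- with_seed(seed, init_patch_embed(patch_size, d[3L], embed_dim,
                                               d[1L], d[2L]))
  }
  fw <- patch_embed_fwd(image, params, patch_size)
  list(tokens = fw$out, n_tokens = nrow(fw$out), params = params)
}

#' Scaled dot-product self-attention over tokens
#'
#' Projects tokens with learnable matrices to queries, keys and values, forms
#' row-stochastic similarity weights `alpha = softmax(q k' / sqrt(d))` and
#' returns the weighted values `y = alpha v`.  Defaults to identity
#' projections, which is convenient for worked examples.
#'
#' @param x `N x D` token matrix.
#' @param Wq,Wk,Wv `D x D` projection matrices (default identity).
#' @return List with `y` (`N x D`), `alpha` (`N x N`, rows summing to 1), and
#'   the projections `q`, `k`, `v`.
#' @export
token_attention <- function(x, Wq = diag(ncol(x)), Wk = diag(ncol(x)),
                            Wv = diag(ncol(x))) {
  at <- attention_fwd(x, Wq, Wk, Wv, 1L)
  list(y = at$out, alpha = at$alphas[[1L]], q = at$q, k = at$k, v = at$v)
}

#' One transformer block
#'
#' Self-attention, residual addition, layer normalisation, a two-layer GELU
#' MLP, residual addition and a second layer normalisation (post-norm
#' ordering).  Output shape equals input shape.
#'
#' @param x `N x D` token matrix.
#' @param params Block parameters (from `init = TRUE` of a previous call or
#'   internal initialisers); fresh ones are drawn when `NULL`.
#' @param mlp_ratio,n_heads,seed Used only when initialising fresh
#'   parameters.
#' @return List with `tokens` and `params`.
#' @export
transformer_block <- function(x, params = NULL, mlp_ratio = 2, n_heads = 1L,
                              seed = 1L) {
  if (is.null(params)) {
    params <- with_seed(seed,
                        init_transformer_block(ncol(x), mlp_ratio, n_heads))
  }
  fw <- transformer_block_fwd(x, params, n_heads)
  list(tokens = fw$out, params = params)
}

#' Reshape global tokens to image geometry
#'
#' Inverse of the patch cut for a single channel: token `t`'s `D = p^2`
#' values fill its source patch in raster order, producing the
#' single-channel global feature map `F0` with the same spatial size as the
#' stage input.  The total of all token values is conserved exactly.
#'
#' @param tokens `N x D` matrix with `N * D == H * W`.
#' @param H,W Output size.
#' @param patch_size Patch side `p`.
#' @return `H x W x 1` array.
#' @export
reshape_global <- function(tokens, H, W, patch_size) {
  reshape_global_fwd(tokens, H, W, patch_size)
}

#' Dilated-convolution local path
#'
#' Four parallel 3x3, stride-1 convolutions with dilations 1, 2, 3 and 5
#' ('same' padding, `w` channels each) are concatenated by channel; a 1x1
#' convolution to `4w` channels is added elementwise.
#'
#' @param feature `H x W x C` input feature map.
#' @param w Branch width (channels per dilated branch).
#' @param params Optional parameters from a previous call.
#' @param seed Seed for fresh initialisation.
#' @return List with `local` (`H x W x 4w`), the branch maps `f1..f4`, the
#'   1x1 map `f5`, and `params`.
#' @export
dilated_local <- function(feature, w, params = NULL, seed = 1L) {
  feature <- as_hwc(feature)
  if (is.null(params)) {
    params <- with_seed(seed, init_dilated_local(dim(feature)[3L], w))
  }
  fw <- dilated_local_fwd(feature, params)
  list(local = fw$out, f1 = fw$f[[1L]], f2 = fw$f[[2L]], f3 = fw$f[[3L]],
       f4 = fw$f[[4L]], f5 = fw$f5, params = params)
}

#' One MSC block
#'
#' Fuses the transformer global path (run on the pooled raw image or NDVI)
#' with the dilated local path (run on the pooled previous-stage feature):
#' the output is `concat(local, F0)` with `4w + 1` channels and the input's
#' spatial size.
#'
#' @param context_input Pooled image or NDVI (`H x W x C`), consumed by the
#'   transformer path.
#' @param prev_feature Pooled previous-stage feature (`H x W x C'`), consumed
#'   by the dilated path; at stage 1 this is the raw input itself.
#' @param w Branch width of the dilated path.
#' @param msc An [msc_config()] (patch size, depth, heads, MLP ratio).
#' @param params Optional stage parameters from a previous call.
#' @param seed Seed for fresh initialisation.
#' @return List with `out` (`H x W x (4w+1)`), `n_tokens`, and `params`.
#' @export
msc_block <- function(context_input, prev_feature, w, msc = msc_config(),
                      params = NULL, seed = 1L) {
  context_input <- as_hwc(context_input)
  prev_feature <- as_hwc(prev_feature)
  if (is.null(params)) {
    params <- with_seed(seed, {
      H <- dim(context_input)[1L]
      list(pe = init_patch_embed(msc$patch_size, dim(context_input)[3L],
                                 msc$embed_dim, H, dim(context_input)[2L]),
           tf = lapply(seq_len(msc$depth), function(d)
             init_transformer_block(msc$embed_dim, msc$mlp_ratio,
                                    msc$n_heads)),
           loc = init_dilated_local(dim(prev_feature)[3L], w))
    })
  }
  fw <- msc_fwd(context_input, prev_feature, params, msc)
  list(out = fw$out, n_tokens = fw$n_tokens, params = params)
}

#' Encode one input branch
#'
#' Builds the five-stage (by default) feature pyramid of one branch: the raw
#' input is repeatedly 2x2 average-pooled to give the stage context inputs,
#' the previous stage's feature is 2x2 max-pooled, and each stage applies an
#' MSC block.  Stage 1 consumes the raw input on both paths.
#'
#' @param x Raw branch input (`H x W x 3` RGB or `H x W x 1` NDVI).
#' @param params Branch parameters (list of per-stage MSC parameters), e.g.
#'   `build_model(cfg)$params$enc_rgb`; fresh ones are drawn when `NULL`.
#' @param cfg A [model_config()].
#' @param seed Seed for fresh initialisation.
#' @return List with `features` (stage features `FA1..FAn`), `sizes` (stage
#'   spatial sides), `n_tokens` (transformer tokens per stage), and `params`.
#' @export
encode_branch <- function(x, params = NULL, cfg = model_config(), seed = 1L) {
  x <- as_hwc(x)
  d <- dim(x)
  check_tile_divisible(d[1L], d[2L], cfg)
  if (is.null(params)) {
    params <- with_seed(seed, init_branch(cfg, d[3L], d[1L]))
  }
  fw <- encode_fwd(x, params, cfg)
  list(features = fw$features, sizes = fw$sizes, n_tokens = fw$n_tokens,
       params = params)
}
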