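#' MSC block configuration
#'
#' Architecture knobs of the Multi-Scale Contextual encoder block: the
#' patch-transformer global path and the dilated-convolution local path.
#'
#' The constraint `embed_dim == patch_size^2` is enforced because the global
#' token matrix is reshaped flat back to image geometry: with `N` tokens of
#' dimension `D = p^2`, `N * D` equals exactly `H * W`, so the reshaped global
#' map `F0` is a single-channel image of the input's size at every stage.
#'
#' @param patch_size Side length `p` of the square patches cut from the stage
#'   input before linear projection (default 16).
#' @param embed_dim Token width `D`; must equal `patch_size^2` (default 256).
#' @param depth Number of stacked transformer blocks per MSC block
#'   (default 6).
#' @param n_heads Attention heads; the formulation is single-head by default.
#' @param mlp_ratio Hidden width of the transformer MLP as a multiple of
#'   `embed_dim` (default 2).
#' @param widths Integer vector, one entry per encoder stage: the width `w`
#'   of each dilated-convolution branch at that stage.  The MSC output has
#'   `4 * w + 1` channels (four concatenated local branches plus the
#'   single-channel global map).
#' @return An object of class `msc_config`.
#' @export
msc_config <- function(patch_size = 16L, embed_dim = patch_size^2,
                       depth = 6L, n_heads = 1L, mlp_ratio = 2,
                       widths = c(8L, 16L, 32L, 64L, 64L)) {
  patch_size <- as.integer(patch_size)
  embed_dim <- as.integer(embed_dim)
  if (embed_dim != patch_size^2) {
    stop("embed_dim must equal patch_size^2 (got D = ", embed_dim,
         ", p = ", patch_size, "): the flat reshape of tokens to the ",
         "single-channel global map requires D = p^2")
  }
  if (depth < 1L) stop("depth must be >= 1")
  if (any(widths < 1L)) stop("branch widths must be positive")
  if (embed_dim %% n_heads != 0L) stop("embed_dim must be divisible by n_heads")
  structure(list(patch_size = patch_size, embed_dim = embed_dim,
                 depth = as.integer(depth), n_heads = as.integer(n_heads),
                 mlp_ratio = mlp_ratio, widths = as.integer(widths)),
            class = "msc_config")
}

#' Full model configuration
#'
#' @param n_stages Number of encoder stages (default 5); each stage halves
#'   the spatial size by 2x2 pooling.
#' @param msc An [msc_config()]; its `widths` must have `n_stages` entries.
#' @param cam_reduction Channel-reduction ratio `r` of the channel-attention
#'   MLP in the decoder (default 8).
#' @param decoder_widths Output channels of the decoder convolution at stages
#'   `1..n_stages-1` (the P-series).  Default `NULL` uses the matching
#'   encoder stage's channel count, `4 * widths[i] + 1`.
#' @param threshold Probability cutoff for binarising predictions
#'   (default 0.5).
#' @param tile_size Square tile side the model is built for (default 256);
#'   the learnable positional embeddings are sized for this tile, so inputs
#'   must match.  Must be divisible by `patch_size * 2^(n_stages - 1)`.
#' @return An object of class `dbmsc_config`.
#' @export
model_config <- function(n_stages = 5L, msc = msc_config(),
                         cam_reduction = 8L, decoder_widths = NULL,
                         threshold = 0.5, tile_size = 256L) {
  n_stages <- as.integer(n_stages)
  if (length(msc$widths) != n_stages) {
    stop("msc$widths must have one entry per stage (", n_stages, ")")
  }
  if (is.null(decoder_widths)) {
    decoder_widths <- 4L * msc$widths[seq_len(n_stages - 1L)] + 1L
  }
  decoder_widths <- as.integer(decoder_widths)
  if (length(decoder_widths) != n_stages - 1L) {
    stop("decoder_widths must have n_stages - 1 entries")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  cfg <- structure(list(n_stages = n_stages, msc = msc,
                        cam_reduction = as.integer(cam_reduction),
                        decoder_widths = decoder_widths,
                        threshold = threshold,
                        tile_size = as.integer(tile_size)),
                   class = "dbmsc_config")
  check_tile_divisible(cfg$tile_size, cfg$tile_size, cfg)
  cfg
}

#' Minimal admissible tile size for a configuration
#'
#' Every stage input must tile cleanly into patches: `H / 2^(i-1)` must be
#' divisible by `patch_size` for stages `i = 1..n_stages`.
#'
#' @param cfg A [model_config()].
#' @return The smallest admissible square tile side (an integer).
#' @export
min_tile_size <- function(cfg) {
  as.integer(cfg$msc$patch_size * 2L^(cfg$n_stages - 1L))
}

check_tile_divisible <- function(H, W, cfg) {
  m <- min_tile_size(cfg)
  if (H %% m != 0L || W %% m != 0L) {
    stop("tile size ", H, "x", W, " is not divisible by patch_size * ",
         "2^(n_stages-1) = ", m, "; the minimal admissible tile is ",
         m, "x", m)
  }
  invisible(TRUE)
}

#' Training configuration
#'
#' Adam with the usual moment decays, initial learning rate 1e-3, and a
#' reduce-on-plateau schedule (halve the rate when validation loss has not
#' improved for `plateau_patience` epochs).
#'
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 5).
#' @param lr Initial learning rate (default 1e-3).
#' @param beta1,beta2 Adam moment decays (defaults 0.9, 0.999).
#' @param plateau_factor,plateau_patience Learning-rate schedule: multiply by
#'   `plateau_factor` after `plateau_patience` epochs without validation-loss
#'   improvement.
#' @param n_repeats Number of repeated runs (seeded independently) for
#'   mean/sd reporting; default 1.
#' @param augment `NULL` to train on tiles as stored, or an [augment_spec()]
#'   applied independently to every tile draw.
#' @param seed Integer seed controlling initialisation, batch order and
#'   augmentation.
#' @param checkpoint_path Where the best-validation model is saved (`NULL`
#'   for no checkpoint file).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 5L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999,
                         plateau_factor = 0.5, plateau_patience = 10L,
                         n_repeats = 1L, augment = NULL, seed = 1L,
                         checkpoint_path = NULL) {
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be positive")
  if (lr <= 0) stop("lr must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 n_repeats = as.integer(n_repeats), augment = augment,
                 seed = as.integer(seed), checkpoint_path = checkpoint_path),
            class = "train_config")
}

#' Read or write a run configuration file
#'
#' One YAML file holding any of the sections `scene`, `msc`, `model`,
#' `train`, `augment`; missing fields fall back to package defaults.
#'
#' @param path File path.
#' @return `read_run_config()` returns a named list with elements `scene`,
#'   `model`, `train`, `augment` (constructed objects).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  msc_args <- raw$msc %||% list()
  msc <- do.call(msc_config, msc_args)
  model_args <- raw$model %||% list()
  model_args$msc <- msc
  model <- do.call(model_config, model_args)
  aug <- if (!is.null(raw$augment)) do.call(augment_spec, raw$augment)
  train_args <- raw$train %||% list()
  train_args$augment <- aug
  train <- do.call(train_config, train_args)
  scene <- do.call(scene_params, raw$scene %||% list())
  list(scene = scene, model = model, train = train, augment = aug)
}

#' @param cfg Named list of sections to serialise (plain lists or the
#'   objects produced by the constructors above).
#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  yaml::write_yaml(lapply(cfg, strip), path)
  invisible(path)
}
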