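# Training loop (Adam + binary cross-entropy + reduce-on-plateau), split
# evaluation, and sliding-tile inference over large rasters.

adam_init <- function(params) {
  list(m = par_zeros_like(params), v = par_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- par_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- par_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- par_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = par_map2(params, upd, `-`), state = state)
}

# One sample's loss gradient at the logits: d(mean BCE o sigmoid)/d(logits).
loss_and_dlogits <- function(fw, mask) {
  p <- fw$prob
  loss <- bce_loss(p, mask)
  n <- length(p)
  dlog <- array((p - mask) / n, dim(fw$logits))
  list(loss = loss, dlogits = dlog)
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

#' Train the network on a dataset manifest
#'
#' Minimises the mean binary cross-entropy over shuffled mini-batches with
#' Adam.  Validation loss and overall accuracy are logged each epoch, the
#' learning rate is halved after `plateau_patience` epochs without
#' validation-loss improvement, and the best-validation weights are kept
#' (when the manifest has no `val` rows, training loss drives the schedule
#' and the final weights are kept).  Fully reproducible given
#' `train_cfg$seed`: initialisation, batch order and augmentation all derive
#' from it.
#'
#' @param manifest Manifest data.frame (see [read_manifest()]) or path to a
#'   manifest CSV; must contain a nonempty `train` split.
#' @param model_cfg A [model_config()] matching the tile size of the data.
#' @param train_cfg A [train_config()].
#' @param verbose Print one structured log line per epoch.
#' @return An object of class `dbmsc_fit`: list with `model` (best weights),
#'   `history` (per-epoch data.frame: epoch, train_loss, val_loss, val_oa,
#'   lr), `best_epoch`, and `config` snapshots.
#' @export
train_model <- function(manifest, model_cfg = model_config(),
                        train_cfg = train_config(), verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  train_tiles <- load_manifest_tiles(manifest, "train")
  val_tiles <- if (any(manifest$split == "val")) {
    load_manifest_tiles(manifest, "val")
  }
  model <- build_model(model_cfg, seed = train_cfg$seed)
  state <- adam_init(model$params)
  lr <- train_cfg$lr
  n <- length(train_tiles)
  hist <- vector("list", train_cfg$epochs)
  best_loss <- Inf
  best_params <- model$params
  best_epoch <- 0L
  stall <- 0L

  with_seed(train_cfg$seed + 1L, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      epoch_losses <- numeric(0)
      epoch_steps <- 0L
      for (bi in batch_indices(n, train_cfg$batch_size)) {
        idx <- ord[bi]
        grads <- NULL
        bloss <- 0
        for (j in idx) {
          s <- train_tiles[[j]]
          if (!is.null(train_cfg$augment)) s <- augment_tile(s, train_cfg$augment)
          fw <- model_fwd(model, s$rgb, s$ndvi, keep_cache = TRUE)
          ld <- loss_and_dlogits(fw, s$mask)
          if (!is.finite(ld$loss)) {
            stop("divergent loss (", ld$loss, ") at epoch ", epoch,
                 ", tile '", s$tile_id, "'")
          }
          g <- model_bwd(model, fw, ld$dlogits)
          grads <- if (is.null(grads)) g else par_add(grads, g)
          bloss <- bloss + ld$loss
        }
        grads <- par_map(grads, function(x) x / length(idx))
        st <- adam_step(model$params, grads, state, lr,
                        train_cfg$beta1, train_cfg$beta2)
        model$params <- st$params
        state <- st$state
        epoch_losses <- c(epoch_losses, bloss / length(idx))
        epoch_steps <- epoch_steps + 1L
      }
      train_loss <- mean(epoch_losses)

      val_loss <- NA_real_
      val_oa <- NA_real_
      if (!is.null(val_tiles)) {
        vl <- 0
        counts <- new_confusion(0, 0, 0, 0)
        for (s in val_tiles) {
          p <- model_fwd(model, s$rgb, s$ndvi)$prob
          vl <- vl + bce_loss(p, s$mask)
          counts <- counts +
            confusion_counts((p >= model_cfg$threshold) * 1, s$mask)
        }
        val_loss <- vl / length(val_tiles)
        val_oa <- seg_scores(counts)$oa
      }
      monitor <- if (is.na(val_loss)) train_loss else val_loss
      if (monitor < best_loss - 1e-12) {
        best_loss <- monitor
        best_params <- model$params
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= train_cfg$plateau_patience) {
          lr <- lr * train_cfg$plateau_factor
          stall <- 0L
        }
      }
      hist[[epoch]] <- data.frame(epoch = epoch, steps = epoch_steps,
                                  train_loss = train_loss,
                                  val_loss = val_loss, val_oa = val_oa,
                                  lr = lr)
      if (verbose) {
        cat(sprintf("epoch=%d train_loss=%.4f val_loss=%s val_oa=%s lr=%g\n",
                    epoch, train_loss,
                    ifelse(is.na(val_loss), "NA", sprintf("%.4f", val_loss)),
                    ifelse(is.na(val_oa), "NA", sprintf("%.4f", val_oa)),
                    lr))
      }
    }
  })

  if (is.null(val_tiles)) {
    best_params <- model$params  # keep final weights without a val monitor
    best_epoch <- train_cfg$epochs
  }
  model$params <- best_params
  if (!is.null(train_cfg$checkpoint_path)) {
    save_checkpoint(model, train_cfg$checkpoint_path)
  }
  structure(list(model = model, history = do.call(rbind, hist),
                 best_epoch = best_epoch, model_config = model_cfg,
                 train_config = train_cfg),
            class = "dbmsc_fit")
}

#' @export
print.dbmsc_fit <- function(x, ...) {
  h <- x$history
  cat("dbmsc_fit: ", nrow(h), " epochs, final train loss ",
      signif(h$train_loss[nrow(h)], 4), ", best epoch ", x$best_epoch,
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a model over a manifest split
#'
#' Runs a forward pass per tile, thresholds at the model's configured
#' cutoff, accumulates confusion counts over the whole split
#' (micro-averaging) and reports [seg_scores()].  With
#' `per_tile = TRUE` a macro average (mean of per-tile scores) is reported
#' alongside.
#'
#' @param model A `dbmsc_model`, a `dbmsc_fit`, or a checkpoint path.
#' @param manifest Manifest data.frame or CSV path.
#' @param split Which split to evaluate (default `"test"`).
#' @param per_tile Also compute per-tile macro-averaged scores.
#' @param report_path Optional path; the report is written there as JSON.
#' @return List with `counts`, `scores`, `n_tiles`, `split`, and optionally
#'   `macro` (per-tile means).
#' @export
evaluate_model <- function(model, manifest, split = "test",
                           per_tile = FALSE, report_path = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "dbmsc_fit")) model <- model$model
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  tiles <- load_manifest_tiles(manifest, split)
  counts <- new_confusion(0, 0, 0, 0)
  tile_scores <- vector("list", length(tiles))
  for (i in seq_along(tiles)) {
    s <- tiles[[i]]
    p <- forward_pass(model, s$rgb, s$ndvi)
    ci <- confusion_counts((p >= model$config$threshold) * 1, s$mask)
    counts <- counts + ci
    if (per_tile) tile_scores[[i]] <- seg_scores(ci)
  }
  report <- list(split = split, n_tiles = length(tiles),
                 counts = unclass(counts)[c("tp", "fp", "tn", "fn", "total")],
                 scores = seg_scores(counts))
  if (per_tile) {
    keys <- c("oa", "f1", "iou", "macro_iou", "kappa")
    report$macro <- lapply(setNames(keys, keys), function(k)
      mean(vapply(tile_scores, `[[`, numeric(1), k)))
  }
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  }
  report
}

# Tiled inference ---------------------------------------------------------

reflect_pad_hw <- function(x, bottom, right) {
  d <- dim(x)
  x[idx_reflect(seq_len(d[1L] + bottom), d[1L]),
    idx_reflect(seq_len(d[2L] + right), d[2L]), , drop = FALSE]
}

#' Predict over a large raster by tiling
#'
#' Partitions a co-registered RGB/NDVI raster pair into model-sized tiles
#' (grid stride `tile - overlap`), reflect-padding the raster so edge tiles
#' reach full size, predicts each tile, averages probabilities where tiles
#' overlap, crops back to the input extent and thresholds.
#'
#' @param model A `dbmsc_model`, `dbmsc_fit`, or checkpoint path.
#' @param rgb `H x W x 3` raster in `[0, 1]`.
#' @param ndvi `H x W` (or `H x W x 1`) raster in `[-1, 1]`.
#' @param tile Tile side (default: the model's configured tile size).
#' @param overlap Overlap between neighbouring tiles in pixels (default 0).
#' @return List with `prob` (`H x W` averaged probabilities) and `mask`
#'   (`H x W` binary prediction).
#' @export
predict_tiles <- function(model, rgb, ndvi, tile = NULL, overlap = 0L) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "dbmsc_fit")) model <- model$model
  tile <- as.integer(tile %||% model$config$tile_size)
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= tile) stop("overlap must be in [0, tile)")
  rgb <- as_hwc(rgb); ndvi <- as_hwc(ndvi)
  d <- dim(rgb)
  if (!identical(dim(ndvi)[1:2], d[1:2])) {
    stop("alignment error: rgb and ndvi rasters differ in size")
  }
  stride <- tile - overlap
  starts_r <- seq(1L, max(d[1L] - overlap, 1L), stride)
  starts_c <- seq(1L, max(d[2L] - overlap, 1L), stride)
  Hp <- max(starts_r) + tile - 1L
  Wp <- max(starts_c) + tile - 1L
  rgb_p <- reflect_pad_hw(rgb, Hp - d[1L], Wp - d[2L])
  ndvi_p <- reflect_pad_hw(ndvi, Hp - d[1L], Wp - d[2L])
  acc <- matrix(0, Hp, Wp)
  cnt <- matrix(0, Hp, Wp)
  for (r in starts_r) {
    for (cc in starts_c) {
      ri <- r + seq_len(tile) - 1L
      ci <- cc + seq_len(tile) - 1L
      p <- forward_pass(model, rgb_p[ri, ci, , drop = FALSE],
                        ndvi_p[ri, ci, , drop = FALSE])
      acc[ri, ci] <- acc[ri, ci] + p
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
  }
  prob <- (acc / cnt)[seq_len(d[1L]), seq_len(d[2L]), drop = FALSE]
  list(prob = prob, mask = (prob >= model$config$threshold) * 1)
}
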