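#' Construct and validate a tile sample
#'
#' A tile sample is one co-registered (RGB, NDVI, mask) triplet: the unit of
#' training and evaluation.  RGB is an `H x W x 3` array in `[0, 1]`, NDVI an
#' `H x W x 1` array in `[-1, 1]`, and the mask an `H x W` binary matrix with
#' 1 marking street-tree canopy.
#'
#' @param rgb `H x W x 3` numeric array in `[0, 1]`.
#' @param ndvi `H x W` matrix or `H x W x 1` array in `[-1, 1]`.
#' @param mask `H x W` binary matrix (`{0, 1}`).
#' @param tile_id Character identifier.
#' @return An object of class `tile_sample`.
#' @export
tile_sample <- function(rgb, ndvi, mask, tile_id = "tile") {
  ndvi <- as_hwc(ndvi)
  if (length(dim(mask)) == 3L) mask <- mask[, , 1L]
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L) {
    stop("rgb must be an H x W x 3 array")
  }
  d <- dim(rgb)[1:2]
  if (!identical(dim(ndvi)[1:2], d) || !identical(dim(mask), d)) {
    stop("alignment error: rgb is ", d[1L], "x", d[2L], " but ndvi is ",
         dim(ndvi)[1L], "x", dim(ndvi)[2L], " and mask is ",
         dim(mask)[1L], "x", dim(mask)[2L])
  }
  if (min(ndvi) < -1 - 1e-6 || max(ndvi) > 1 + 1e-6) {
    stop("range error: NDVI values outside [-1, 1] (observed range [",
         signif(min(ndvi), 4), ", ", signif(max(ndvi), 4), "])")
  }
  if (!is_binary_array(mask)) stop("mask must be binary {0, 1}")
  storage.mode(rgb) <- "double"
  storage.mode(ndvi) <- "double"
  storage.mode(mask) <- "double"
  structure(list(rgb = rgb, ndvi = ndvi, mask = mask,
                 tile_id = as.character(tile_id)),
            class = "tile_sample")
}

#' @export
print.tile_sample <- function(x, ...) {
  d <- dim(x$rgb)
  cat("tile_sample '", x$tile_id, "': ", d[1L], "x", d[2L],
      ", canopy fraction ", signif(mean(x$mask), 3), "\n", sep = "")
  invisible(x)
}

read_raster <- function(path, what = c("rgb", "ndvi", "mask")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop("I/O error: cannot read '", path, "'")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    npy = read_npy(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading '", path, "' requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop("I/O error: unsupported raster format '", ext, "' for '", path, "'")
  )
  if (what == "rgb") {
    if (length(dim(img)) != 3L || dim(img)[3L] < 3L) {
      stop("I/O error: '", path, "' is not a 3-band raster")
    }
    img <- img[, , 1:3, drop = FALSE]  # drop alpha if present
  } else {
    if (length(dim(img)) == 3L) {
      if (dim(img)[3L] != 1L) stop("I/O error: '", path, "' is not single-band")
      img <- img[, , 1L]
    }
  }
  img
}

#' Load a tile triplet from disk
#'
#' RGB tiles are read from 8-bit PNG or TIFF (values rescaled to `[0, 1]` by
#' the image reader); NDVI from NPY (float, lossless) or float TIFF, passed
#' through unchanged; masks from single-band PNG/TIFF and binarised (any
#' nonzero value becomes 1).  NDVI values outside `[-1, 1]` beyond a 1e-6
#' tolerance raise an error rather than being clipped, and a size mismatch
#' between the three rasters raises an alignment error.
#'
#' @param rgb_path,ndvi_path,mask_path File paths.
#' @param tile_id Identifier; defaults to the RGB file stem.
#' @return A [tile_sample()].
#' @export
load_tile <- function(rgb_path, ndvi_path, mask_path,
                      tile_id = tools::file_path_sans_ext(basename(rgb_path))) {
  rgb <- read_raster(rgb_path, "rgb")
  ndvi <- read_raster(ndvi_path, "ndvi")
  mask <- read_raster(mask_path, "mask")
  mask <- (mask != 0) * 1
  tile_sample(rgb, ndvi, mask, tile_id)
}

#' Write a tile triplet to disk
#'
#' RGB and mask as 8-bit PNG; NDVI as NPY (float64, exact round-trip).
#'
#' @param sample A [tile_sample()].
#' @param rgb_path,ndvi_path,mask_path Output paths (`.png`, `.npy`, `.png`).
#' @return Invisibly, the three paths.
#' @export
write_tile <- function(sample, rgb_path, ndvi_path, mask_path) {
  png::writePNG(sample$rgb, rgb_path)
  write_npy(sample$ndvi[, , 1L], ndvi_path)
  png::writePNG(sample$mask, mask_path)
  invisible(c(rgb_path, ndvi_path, mask_path))
}

# Geometric transforms ----------------------------------------------------
# Every geometric transform is applied identically to rgb, ndvi and mask so
# the label stays registered to the imagery.

rot90_mat <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m[nrow(m):1L, , drop = FALSE])
  m
}

apply_bands <- function(sample, f) {
  rgb <- sample$rgb
  for (ch in 1:3) rgb[, , ch] <- f(sample$rgb[, , ch])
  ndvi <- sample$ndvi
  ndvi[, , 1L] <- f(sample$ndvi[, , 1L])
  list(rgb = rgb, ndvi = ndvi)
}

#' Deterministic tile transforms
#'
#' Building blocks of the augmentation pipeline, exposed for direct use:
#' `flip_tile` mirrors horizontally (`axis = "h"`, left-right) or vertically
#' (`axis = "v"`, top-bottom); `rotate_tile` rotates counter-clockwise by
#' `k * 90` degrees; `shift_tile` translates by whole pixels with reflected
#' borders for rgb/ndvi and zero fill for the mask.
#'
#' @param sample A [tile_sample()].
#' @param axis `"h"` or `"v"`.
#' @return A transformed [tile_sample()].
#' @export
flip_tile <- function(sample, axis = c("h", "v")) {
  axis <- match.arg(axis)
  f <- if (axis == "h") function(m) m[, ncol(m):1L, drop = FALSE]
       else function(m) m[nrow(m):1L, , drop = FALSE]
  b <- apply_bands(sample, f)
  tile_sample(b$rgb, b$ndvi, f(sample$mask), sample$tile_id)
}

#' @param k Number of 90-degree counter-clockwise quarter turns.
#' @rdname flip_tile
#' @export
rotate_tile <- function(sample, k) {
  f <- function(m) rot90_mat(m, k)
  b <- apply_bands(sample, f)
  tile_sample(b$rgb, b$ndvi, f(sample$mask), sample$tile_id)
}

#' @param dr,dc Shift in rows/columns (positive moves content down/right).
#' @rdname flip_tile
#' @export
shift_tile <- function(sample, dr, dc) {
  d <- dim(sample$mask)
  src_r <- seq_len(d[1L]) - as.integer(dr)
  src_c <- seq_len(d[2L]) - as.integer(dc)
  refl <- function(m) m[idx_reflect(src_r, d[1L]), idx_reflect(src_c, d[2L]),
                        drop = FALSE]
  zfill <- function(m) {
    out <- matrix(0, d[1L], d[2L])
    ok_r <- src_r >= 1L & src_r <= d[1L]
    ok_c <- src_c >= 1L & src_c <= d[2L]
    out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
    out
  }
  b <- apply_bands(sample, refl)
  tile_sample(b$rgb, b$ndvi, zfill(sample$mask), sample$tile_id)
}

rotate_tile_arbitrary <- function(sample, angle_deg) {
  d <- dim(sample$mask)
  th <- angle_deg * pi / 180
  cy <- (d[1L] + 1) / 2; cx <- (d[2L] + 1) / 2
  r <- matrix(seq_len(d[1L]), d[1L], d[2L])
  c <- matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)
  # inverse map, nearest neighbour
  sr <- round(cy + cos(th) * (r - cy) - sin(th) * (c - cx))
  sc <- round(cx + sin(th) * (r - cy) + cos(th) * (c - cx))
  inside <- sr >= 1 & sr <= d[1L] & sc >= 1 & sc <= d[2L]
  pick <- function(m, fill) {
    out <- matrix(fill, d[1L], d[2L])
    out[inside] <- m[cbind(sr[inside], sc[inside])]
    out
  }
  rgb <- sample$rgb
  for (ch in 1:3) rgb[, , ch] <- pick(sample$rgb[, , ch], mean(sample$rgb[, , ch]))
  ndvi <- sample$ndvi
  ndvi[, , 1L] <- pick(sample$ndvi[, , 1L], mean(sample$ndvi[, , 1L]))
  tile_sample(rgb, ndvi, pick(sample$mask, 0), sample$tile_id)
}

#' Augmentation specification
#'
#' Random shifts, rotations, horizontal/vertical flips and RGB brightness
#' jitter.  Geometric transforms are applied jointly to rgb, ndvi and mask;
#' brightness jitter multiplies the RGB bands by a factor drawn uniformly
#' from `[1 - brightness_frac, 1 + brightness_frac]` (then clips to
#' `[0, 1]`) and never touches NDVI or the mask.
#'
#' @param shift_frac Maximum translation as a fraction of the tile side
#'   (default 0.1); reflected borders for rgb/ndvi, zero fill for the mask.
#' @param rotation_mode `"multiples_of_90"` (default; exact, no
#'   interpolation) or `"arbitrary"` (nearest-neighbour resampling).
#' @param rotate Enable random rotation (default TRUE).
#' @param flip_h,flip_v Enable the corresponding flip, applied with
#'   probability 1/2 each.
#' @param brightness_frac Maximum relative RGB jitter (default 0.1,
#'   i.e. up to +/-10 percent).
#' @param seed Optional integer; when set, [augment_tile()] is deterministic
#'   for this spec regardless of the surrounding RNG state.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(shift_frac = 0.1,
                         rotation_mode = c("multiples_of_90", "arbitrary"),
                         rotate = TRUE, flip_h = TRUE, flip_v = TRUE,
                         brightness_frac = 0.1, seed = NULL) {
  rotation_mode <- match.arg(rotation_mode)
  if (shift_frac >= 1 || shift_frac < 0) stop("shift_frac must be in [0, 1)")
  if (brightness_frac >= 1 || brightness_frac < 0) {
    stop("brightness_frac must be in [0, 1)")
  }
  structure(list(shift_frac = shift_frac, rotation_mode = rotation_mode,
                 rotate = rotate, flip_h = flip_h, flip_v = flip_v,
                 brightness_frac = brightness_frac, seed = seed),
            class = "augment_spec")
}

#' Randomly augment a tile
#'
#' Draws one random shift, rotation, flip pair and brightness factor
#' according to `spec` and applies them; see [augment_spec()] for the
#' guarantees.  Deterministic given `spec$seed` (or the surrounding RNG
#' state when `spec$seed` is `NULL`).
#'
#' @param sample A [tile_sample()].
#' @param spec An [augment_spec()].
#' @return An augmented [tile_sample()].
#' @export
augment_tile <- function(sample, spec) {
  stopifnot(inherits(spec, "augment_spec"))
  with_seed(spec$seed, {
    d <- dim(sample$mask)
    out <- sample
    if (spec$shift_frac > 0) {
      mr <- floor(spec$shift_frac * d[1L])
      mc <- floor(spec$shift_frac * d[2L])
      out <- shift_tile(out, sample.int(2L * mr + 1L, 1L) - mr - 1L,
                        sample.int(2L * mc + 1L, 1L) - mc - 1L)
    }
    if (isTRUE(spec$rotate)) {
      if (spec$rotation_mode == "multiples_of_90") {
        out <- rotate_tile(out, sample.int(4L, 1L) - 1L)
      } else {
        out <- rotate_tile_arbitrary(out, runif(1L, 0, 360))
      }
    }
    if (spec$flip_h && runif(1L) < 0.5) out <- flip_tile(out, "h")
    if (spec$flip_v && runif(1L) < 0.5) out <- flip_tile(out, "v")
    if (spec$brightness_frac > 0) {
      f <- runif(1L, 1 - spec$brightness_frac, 1 + spec$brightness_frac)
      out$rgb <- pmin(pmax(out$rgb * f, 0), 1)
    }
    out
  })
}

# Manifests ---------------------------------------------------------------

#' Randomly split tile ids into train/val/test
#'
#' Per-split counts are `round(n * ratio / sum(ratios))` with any rounding
#' remainder assigned to the training split; the partition is disjoint,
#' exhaustive, and deterministic given `seed`.
#'
#' @param tile_ids Character vector of unique tile ids (length >= 3).
#' @param ratios Positive numeric triple, default `c(8, 1, 1)`.
#' @param seed Integer seed.
#' @return A data.frame with columns `tile_id`, `split`.
#' @export
split_manifest <- function(tile_ids, ratios = c(8, 1, 1), seed = 1L) {
  n <- length(tile_ids)
  if (anyDuplicated(tile_ids)) stop("tile_ids must be unique")
  if (n < 3L) stop("size error: need at least 3 tiles to form 3 splits")
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stop("ratios must be 3 positive numbers")
  }
  n_val <- round(n * ratios[2L] / sum(ratios))
  n_test <- round(n * ratios[3L] / sum(ratios))
  n_val <- max(1L, n_val); n_test <- max(1L, n_test)
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop("size error: ratios leave no training tiles")
  perm <- with_seed(seed, sample(tile_ids))
  split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  out <- data.frame(tile_id = perm, split = split,
                    stringsAsFactors = FALSE)
  out[order(match(out$tile_id, tile_ids)), , drop = FALSE]
}

#' Read or write a dataset manifest
#'
#' A manifest is a CSV with header
#' `tile_id,rgb_path,ndvi_path,mask_path,split`.  Paths are stored relative
#' to the manifest's directory so a dataset folder can be moved wholesale;
#' `read_manifest()` resolves them and verifies every file exists.
#'
#' @param path Manifest CSV path.
#' @param check_paths Verify referenced files exist (default TRUE).
#' @return A data.frame with resolved absolute paths and a `split` column.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tile_id", "rgb_path", "ndvi_path", "mask_path", "split")
  if (!all(need %in% names(m))) {
    stop("manifest ", path, " must have columns ", paste(need, collapse = ","))
  }
  base <- dirname(normalizePath(path))
  for (col in c("rgb_path", "ndvi_path", "mask_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  if (check_paths) {
    all_paths <- c(m$rgb_path, m$ndvi_path, m$mask_path)
    missing <- all_paths[!file.exists(all_paths)]
    if (length(missing) > 0L) {
      stop("manifest references missing files: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  m
}

#' @param manifest Data.frame with the five manifest columns; paths may be
#'   absolute (they are relativised against the manifest directory when
#'   possible).
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  base <- normalizePath(dirname(path))
  m <- manifest
  for (col in c("rgb_path", "ndvi_path", "mask_path")) {
    pref <- paste0(base, "/")
    abs <- startsWith(m[[col]], pref)
    m[[col]][abs] <- substring(m[[col]][abs], nchar(pref) + 1L)
  }
  write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

load_manifest_tiles <- function(manifest, split = NULL) {
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  if (nrow(manifest) == 0L) stop("no tiles in requested split")
  lapply(seq_len(nrow(manifest)), function(i) {
    load_tile(manifest$rgb_path[i], manifest$ndvi_path[i],
              manifest$mask_path[i], manifest$tile_id[i])
  })
}
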