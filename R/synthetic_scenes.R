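#' Synthetic street-scene parameters
#'
#' Controls for the fully synthetic tile generator that emulates the
#' statistical structure the segmentation task targets: street-tree canopies
#' in two size regimes (concentrated large crowns and scattered small ones)
#' placed along a road corridor, high-NDVI grass distractors away from the
#' road, a fraction of tiles with no trees at all, and per-tile illumination
#' variability.  Defaults mirror the study conditions: 256-pixel tiles,
#' roughly 11 percent empty tiles, and canopy radii spanning more than a
#' five-fold size range.
#'
#' @param tile_size Square tile side in pixels (default 256).
#' @param small_radius_range,large_radius_range Canopy radius ranges in
#'   pixels (defaults 2-6 and 12-40).
#' @param p_large Probability that a canopy is drawn from the large regime
#'   (default 0.3).
#' @param trees_per_tile_range Range of canopy counts for non-empty tiles
#'   (default 3-25).
#' @param empty_tile_frac Fraction of tiles with no trees (default 0.11).
#' @param grass_patch_prob Probability that a tile contains grass distractor
#'   patches (default 0.5).  Grass shares the tree NDVI distribution but is
#'   mask = 0, so NDVI thresholding alone cannot solve the task.
#' @param ndvi_veg_range NDVI range of vegetated pixels (default 0.55-0.90).
#' @param ndvi_impervious_range NDVI range of road/background pixels
#'   (default -0.15-0.20).
#' @param rgb_noise_sd Gaussian noise s.d. added to RGB (default 0.03).
#' @param seed Default seed for dataset-level generation.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(tile_size = 256L,
                         small_radius_range = c(2, 6),
                         large_radius_range = c(12, 40),
                         p_large = 0.3,
                         trees_per_tile_range = c(3L, 25L),
                         empty_tile_frac = 0.11,
                         grass_patch_prob = 0.5,
                         ndvi_veg_range = c(0.55, 0.90),
                         ndvi_impervious_range = c(-0.15, 0.20),
                         rgb_noise_sd = 0.03,
                         seed = 1L) {
  ordered <- function(r) length(r) == 2L && r[1L] <= r[2L]
  stopifnot(ordered(small_radius_range), ordered(large_radius_range),
            ordered(trees_per_tile_range), ordered(ndvi_veg_range),
            ordered(ndvi_impervious_range))
  for (p in c(p_large, empty_tile_frac, grass_patch_prob)) {
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  }
  if (min(ndvi_veg_range) < -1 || max(ndvi_veg_range) > 1 ||
      min(ndvi_impervious_range) < -1 || max(ndvi_impervious_range) > 1) {
    stop("NDVI ranges must lie within [-1, 1]")
  }
  if (2 * max(large_radius_range, small_radius_range) >= tile_size) {
    stop("canopy radius ranges must fit inside the tile")
  }
  structure(list(tile_size = as.integer(tile_size),
                 small_radius_range = small_radius_range,
                 large_radius_range = large_radius_range,
                 p_large = p_large,
                 trees_per_tile_range = as.integer(trees_per_tile_range),
                 empty_tile_frac = empty_tile_frac,
                 grass_patch_prob = grass_patch_prob,
                 ndvi_veg_range = ndvi_veg_range,
                 ndvi_impervious_range = ndvi_impervious_range,
                 rgb_noise_sd = rgb_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_params")
}

runif1 <- function(range) runif(1L, range[1L], range[2L])

# Bimodal canopy radius draw (exposed internally for distribution tests).
sample_canopy_radius <- function(params, n = 1L) {
  large <- runif(n) < params$p_large
  r <- numeric(n)
  r[large] <- runif(sum(large), params$large_radius_range[1L],
                    params$large_radius_range[2L])
  r[!large] <- runif(sum(!large), params$small_radius_range[1L],
                     params$small_radius_range[2L])
  r
}

# Anti-aliased ellipse coverage in [0, 1]: 1 deep inside, 0 outside, linear
# ramp about one pixel wide across the boundary.
ellipse_coverage <- function(rr, cc, cy, cx, a, b, phi) {
  dr <- rr - cy
  dc <- cc - cx
  u <- (dc * cos(phi) + dr * sin(phi)) / a
  v <- (-dc * sin(phi) + dr * cos(phi)) / b
  de <- sqrt(u^2 + v^2)
  pmin(1, pmax(0, (1 - de) * min(a, b) + 0.5))
}

#' Generate one synthetic street-scene tile
#'
#' A low-NDVI gray road corridor crosses the tile; street-tree canopies
#' (anti-aliased ellipses, binarised at 0.5 coverage for the mask) are placed
#' within a buffer of the corridor with radii from the bimodal small/large
#' mixture; grass patches with tree-like NDVI but different RGB may appear
#' away from the corridor and are labelled background.  Canopy placement
#' stops if it would exceed 55 percent tile coverage.  Bit-identical output
#' for identical `(params, seed)`.
#'
#' @param params A [scene_params()].
#' @param seed Integer seed.
#' @param tile_id Identifier for the resulting sample.
#' @return A [tile_sample()].
#' @export
generate_scene <- function(params, seed = params$seed, tile_id = "scene") {
  stopifnot(inherits(params, "scene_params"))
  S <- params$tile_size
  with_seed(seed, {
    rr <- matrix(seq_len(S), S, S)
    cc <- matrix(seq_len(S), S, S, byrow = TRUE)

    # road corridor: band around a line through a random interior point
    theta <- sample(c(0, 45, 90, 135), 1L) * pi / 180
    cy <- runif(1L, 0.3, 0.7) * S
    cx <- runif(1L, 0.3, 0.7) * S
    halfwidth <- max(2, round(S * runif(1L, 0.03, 0.06)))
    dist_road <- abs((rr - cy) * cos(theta) - (cc - cx) * sin(theta))
    road <- dist_road <= halfwidth

    # canopies along the corridor
    canopy_cov <- matrix(0, S, S)
    empty <- runif(1L) < params$empty_tile_frac
    n_trees <- if (empty) 0L else {
      rng <- params$trees_per_tile_range
      if (rng[1L] == rng[2L]) rng[1L] else sample(seq(rng[1L], rng[2L]), 1L)
    }
    buffer <- 0.15 * S
    for (i in seq_len(n_trees)) {
      if (mean(canopy_cov >= 0.5) > 0.55) break
      a <- sample_canopy_radius(params, 1L)
      b <- a * runif(1L, 0.8, 1.2)
      phi <- runif(1L, 0, pi)
      # a point on the centreline, offset to one side of the road
      t_along <- runif(1L, -0.7, 0.7) * S
      side <- sample(c(-1, 1), 1L)
      off <- halfwidth + runif(1L, 0, buffer) + 0.5 * a
      py <- cy + t_along * sin(theta) + side * off * cos(theta)
      px <- cx + t_along * cos(theta) - side * off * sin(theta)
      py <- min(max(py, a + 1), S - a)
      px <- min(max(px, a + 1), S - a)
      canopy_cov <- pmax(canopy_cov, ellipse_coverage(rr, cc, py, px, a, b, phi))
    }
    mask <- (canopy_cov >= 0.5) * 1

    # grass distractors away from the corridor
    grass_cov <- matrix(0, S, S)
    if (runif(1L) < params$grass_patch_prob) {
      for (i in seq_len(sample(1:3, 1L))) {
        ga <- runif(1L, 0.05, 0.15) * S
        gb <- ga * runif(1L, 0.6, 1.4)
        for (try in 1:20) {
          gy <- runif(1L, ga, S - ga)
          gx <- runif(1L, ga, S - ga)
          d <- abs((gy - cy) * cos(theta) - (gx - cx) * sin(theta))
          if (d > halfwidth + 0.2 * S) break
        }
        grass_cov <- pmax(grass_cov,
                          ellipse_coverage(rr, cc, gy, gx, ga, gb,
                                           runif(1L, 0, pi)))
      }
      grass_cov <- grass_cov * (1 - canopy_cov)
    }

    # NDVI: impervious base, vegetation values blended in by coverage
    base_ndvi <- runif1(params$ndvi_impervious_range)
    road_ndvi <- runif1(params$ndvi_impervious_range)
    ndvi <- matrix(base_ndvi, S, S)
    ndvi[road] <- road_ndvi
    veg_tree <- runif1(params$ndvi_veg_range)
    veg_grass <- runif1(params$ndvi_veg_range)
    ndvi <- ndvi * (1 - canopy_cov) + veg_tree * canopy_cov
    ndvi <- ndvi * (1 - grass_cov) + veg_grass * grass_cov
    ndvi <- ndvi + matrix(rnorm(S * S, sd = 0.02), S, S)
    ndvi <- pmin(pmax(ndvi, -1), 1)

    # RGB: gray road, brownish background, dark-green canopy, light grass
    bg <- c(0.55, 0.52, 0.45) * runif(1L, 0.9, 1.1)
    road_col <- c(0.45, 0.45, 0.46) * runif(1L, 0.9, 1.1)
    tree_col <- c(0.13, 0.33, 0.12) * runif(1L, 0.85, 1.15)
    grass_col <- c(0.40, 0.58, 0.25) * runif(1L, 0.85, 1.15)
    illum <- runif(1L, 0.85, 1.15)  # acquisition-time brightness
    rgb <- array(0, c(S, S, 3L))
    for (ch in 1:3) {
      m <- matrix(bg[ch], S, S)
      m[road] <- road_col[ch]
      m <- m * (1 - grass_cov) + grass_col[ch] * grass_cov
      m <- m * (1 - canopy_cov) + tree_col[ch] * canopy_cov
      rgb[, , ch] <- m * illum + matrix(rnorm(S * S, sd = params$rgb_noise_sd), S, S)
    }
    rgb <- pmin(pmax(rgb, 0), 1)

    out <- tile_sample(rgb, ndvi, mask, tile_id)
    attr(out, "road") <- road
    out
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_tiles` tile triplets (PNG/NPY/PNG) under `out_dir` plus a
#' `manifest.csv` with an 8:1:1 train/val/test split (ratios configurable).
#' Per-tile seeds are derived from `seed`, so regenerating with the same
#' arguments reproduces the files bit for bit.
#'
#' @param params A [scene_params()].
#' @param n_tiles Number of tiles (>= 3).
#' @param out_dir Output directory (created if needed).
#' @param ratios Split ratios, default `c(8, 1, 1)`.
#' @param seed Integer seed.
#' @return The manifest data.frame (paths resolved), invisibly also written
#'   to `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(params, n_tiles, out_dir,
                             ratios = c(8, 1, 1), seed = params$seed) {
  if (n_tiles < 3L) stop("n_tiles must be at least 3")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create '", out_dir, "'")
  out_dir <- normalizePath(out_dir)
  ids <- sprintf("tile_%04d", seq_len(n_tiles))
  rows <- vector("list", n_tiles)
  for (i in seq_len(n_tiles)) {
    s <- generate_scene(params, seed = seed + i, tile_id = ids[i])
    rgb_p <- file.path(out_dir, paste0(ids[i], "_rgb.png"))
    ndvi_p <- file.path(out_dir, paste0(ids[i], "_ndvi.npy"))
    mask_p <- file.path(out_dir, paste0(ids[i], "_mask.png"))
    write_tile(s, rgb_p, ndvi_p, mask_p)
    rows[[i]] <- data.frame(tile_id = ids[i], rgb_path = rgb_p,
                            ndvi_path = ndvi_p, mask_path = mask_p,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  sp <- split_manifest(ids, ratios = ratios, seed = seed)
  manifest$split <- sp$split[match(manifest$tile_id, sp$tile_id)]
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
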