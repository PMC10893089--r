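# Shared fixtures: reduced-scale configurations and synthetic data builders.
# All tests run on desk-scale geometry (16-64 px tiles); the architecture is
# size-agnostic apart from the positional embeddings.

# Smallest config that exercises every code path (3 stages, 16 px tiles).
tiny_cfg <- function() {
  model_config(n_stages = 3L,
               msc = msc_config(patch_size = 2L, embed_dim = 4L, depth = 1L,
                                widths = c(2L, 2L, 2L)),
               tile_size = 16L)
}

# Reduced training config: 64 px tiles, p = 4, D = 16, depth 2,
# widths 4/8/8/8/8 -- the scaled-down trainability setting.
small_cfg <- function() {
  model_config(n_stages = 5L,
               msc = msc_config(patch_size = 4L, embed_dim = 16L, depth = 2L,
                                widths = c(4L, 8L, 8L, 8L, 8L)),
               tile_size = 64L)
}

# Scene parameters scaled to 64 px tiles (canopy radii shrunk with the tile
# so the two size regimes still fit and stay well separated).
small_scene_params <- function(...) {
  scene_params(tile_size = 64L,
               small_radius_range = c(1.5, 3),
               large_radius_range = c(6, 12),
               ...)
}

rand_tile <- function(seed = 1L, S = 16L) {
  set.seed(seed)
  tile_sample(array(runif(S * S * 3), c(S, S, 3L)),
              matrix(runif(S * S, -1, 1), S, S),
              matrix(rbinom(S * S, 1L, 0.3), S, S),
              paste0("rand", seed))
}

# Deep-index perturbation of one scalar in a parameter tree ("a.2.W" paths
# as produced by par_flatten), used by finite-difference gradient checks.
perturb_param <- function(params, path_str, j, delta) {
  path <- lapply(strsplit(path_str, ".", fixed = TRUE)[[1L]],
                 function(s) if (grepl("^[0-9]+$", s)) as.integer(s) else s)
  rec <- function(p, pth) {
    if (length(pth) == 1L) {
      p[[pth[[1L]]]][j] <- p[[pth[[1L]]]][j] + delta
      return(p)
    }
    p[[pth[[1L]]]] <- rec(p[[pth[[1L]]]], pth[-1L])
    p
  }
  rec(params, path)
}

expect_rel_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)) / max(1e-8, max(abs(b))), tol)
}
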