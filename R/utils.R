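`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  seed = NULL runs on the current stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", globalenv(), inherits = FALSE)) set.seed(NULL)
    old <- get(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

cache_get <- function(key, builder) {
  if (!exists(key, .dbmsc_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .dbmsc_cache)
  }
  get(key, .dbmsc_cache, inherits = FALSE)
}

# Channel helpers --------------------------------------------------------

as_hwc <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# Concatenate H x W x C arrays along the channel axis.  Channels are the last
# dimension, so plain c() already produces the right memory layout.
concat_ch <- function(...) {
  arrs <- lapply(list(...), as_hwc)
  d <- dim(arrs[[1L]])
  cs <- vapply(arrs, function(a) dim(a)[3L], integer(1))
  for (a in arrs) {
    stopifnot(dim(a)[1L] == d[1L], dim(a)[2L] == d[2L])
  }
  array(unlist(arrs, use.names = FALSE), c(d[1L], d[2L], sum(cs)))
}

take_ch <- function(x, ch) x[, , ch, drop = FALSE]

# Recursive parameter-tree helpers (parameters are nested named lists whose
# leaves are numeric arrays/matrices/vectors).
par_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) par_map2(x, y, f), a, b)
    return(out)
  }
  f(a, b)
}

par_map <- function(a, f) {
  if (is.list(a)) return(lapply(a, par_map, f = f))
  f(a)
}

par_add <- function(a, b) par_map2(a, b, `+`)

par_zeros_like <- function(a) par_map(a, function(x) x * 0)

par_count <- function(a) {
  if (is.list(a)) return(sum(vapply(a, par_count, numeric(1))))
  length(a)
}

# Flatten a parameter tree to a named list of leaves ("a.b.c" paths).
par_flatten <- function(a, prefix = NULL) {
  if (!is.list(a)) {
    out <- list(a)
    names(out) <- prefix %||% "par"
    return(out)
  }
  nms <- names(a) %||% as.character(seq_along(a))
  nms[nms == ""] <- as.character(seq_along(a))[nms == ""]
  out <- list()
  for (i in seq_along(a)) {
    p <- if (is.null(prefix)) nms[i] else paste(prefix, nms[i], sep = ".")
    out <- c(out, par_flatten(a[[i]], p))
  }
  out
}

# Reflected index into 1..n (triangular wave), valid for any integer i.
idx_reflect <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * (n - 1L))
  j <- ifelse(j >= n, 2L * (n - 1L) - j, j)
  as.integer(j + 1L)
}

is_binary_array <- function(x) all(x == 0 | x == 1)
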