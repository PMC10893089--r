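# Minimal NPY (format version 1.0) reader/writer for 2-D float arrays, used
# to persist NDVI rasters losslessly (8-bit image formats would quantise the
# [-1, 1] range).  Little-endian '<f8'/'<f4' only, which covers what this
# package writes and what numpy.save produces for float rasters.

write_npy <- function(x, path) {
  if (!is.matrix(x)) stop("write_npy expects a 2-D matrix")
  shape <- paste0("(", nrow(x), ", ", ncol(x), ")")
  header <- paste0("{'descr': '<f8', 'fortran_order': False, 'shape': ",
                   shape, ", }")
  # magic(6) + version(2) + header-length(2) + header, padded to 64 bytes
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  # NPY default is C (row-major) order
  writeBin(as.vector(t(x)), con, size = 8L, endian = "little")
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop("not an NPY file: ", path)
  }
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shp <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shp), ",")[[1L]])
  dims <- dims[!is.na(dims)]
  if (length(dims) != 2L) stop("read_npy supports 2-D arrays only: ", path)
  size <- switch(descr, "<f8" = 8L, "<f4" = 4L,
                 stop("unsupported NPY dtype '", descr, "' in ", path))
  vals <- readBin(con, "double", prod(dims), size = size, endian = "little")
  if (fortran) matrix(vals, dims[1L], dims[2L])
  else t(matrix(vals, dims[2L], dims[1L]))
}
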