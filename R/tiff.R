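# Minimal baseline TIFF I/O (little-endian, uncompressed, single-sample
# grayscale, multi-page). No TIFF package ships with the supported
# environment, and the image stacks this package reads and writes are its
# own renders, so a baseline codec is sufficient: 8/16-bit unsigned and
# 32-bit float samples, one strip per page.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_byte_counts = 279L, sample_format = 339L)

#' Write a grayscale (multi-page) TIFF
#'
#' @param images a numeric matrix or list of matrices (rows = image rows,
#'   top first). Values are written as 32-bit floats by default.
#' @param path output file.
#' @param bits 8, 16 (unsigned integer, values clipped to `[0, 1]` and
#'   scaled) or 32 (float, raw values).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(images, path, bits = 32) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(bits %in% c(8, 16, 32))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # first IFD offset placeholder, patched as we go: header is 8 bytes
  offset <- 8
  writeBin(as.integer(offset), con, size = 4, endian = "little")
  n_entries <- length(TIFF_TAGS)
  for (p in seq_along(images)) {
    m <- images[[p]]
    h <- nrow(m); w <- ncol(m)
    bytes <- w * h * bits / 8
    ifd_off <- offset  # IFD first, data after
    data_off <- ifd_off + 2 + n_entries * 12 + 4
    entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
    writeBin(as.integer(n_entries), con, size = 2, endian = "little")
    entry(256, 4, 1, w)
    entry(257, 4, 1, h)
    entry(258, 3, 1, bits)
    entry(259, 3, 1, 1)               # no compression
    entry(262, 3, 1, 1)               # black is zero
    entry(273, 4, 1, data_off)
    entry(278, 4, 1, h)               # one strip
    entry(279, 4, 1, bytes)
    entry(339, 3, 1, if (bits == 32) 3 else 1)
    next_ifd <- if (p < length(images)) data_off + bytes else 0
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    v <- as.numeric(t(m))
    if (bits == 32) {
      writeBin(v, con, size = 4, endian = "little")
    } else {
      scale <- 2^bits - 1
      iv <- as.integer(round(pmin(pmax(v, 0), 1) * scale))
      writeBin(iv, con, size = bits / 8, endian = "little")
    }
    offset <- data_off + bytes
  }
  invisible(path)
}

#' Read a grayscale (multi-page) TIFF written by [write_tiff()]
#'
#' Supports little-endian uncompressed single-sample pages with 8/16-bit
#' unsigned or 32-bit float samples (integer data is rescaled to `[0, 1]`).
#'
#' @param path file path.
#' @return list of numeric matrices.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42)
    stop_magsense("not a little-endian TIFF", "magsense_io_error")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2 + (i - 1) * 12
      tags[[as.character(u16(e))]] <- u32(e + 8)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop_magsense(
          sprintf("missing TIFF tag %d", tag), "magsense_io_error")
        default
      } else v
    }
    if (g(259, 1) != 1)
      stop_magsense("compressed TIFF not supported", "magsense_io_error")
    w <- g(256); h <- g(257); bits <- g(258, 1)
    # 16-bit short values are stored in the low bytes of the value field
    if (bits > 65535) bits <- bits %% 65536
    off <- g(273); fmt <- g(339, 1) %% 65536
    nv <- w * h
    if (bits == 32 && fmt == 3) {
      v <- readBin(raw[off + seq_len(4 * nv)], "double", nv, size = 4,
                   endian = "little")
    } else if (bits %in% c(8, 16)) {
      v <- readBin(raw[off + seq_len(bits / 8 * nv)], "integer", nv,
                   size = bits / 8, signed = FALSE, endian = "little")
      v <- v / (2^bits - 1)
    } else stop_magsense("unsupported TIFF sample layout", "magsense_io_error")
    pages[[length(pages) + 1]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  pages
}
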