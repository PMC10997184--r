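# Minimal PNG reader/writer for label masks and grayscale slices.
# No PNG package is available in the supported environment, so the subset of
# the format this pipeline needs is implemented directly: 8/4/2/1-bit,
# grayscale (colour type 0) or paletted (colour type 3), non-interlaced,
# all five scanline filters on read, filter 0 on write. Compression uses
# base R's zlib bindings (memCompress/memDecompress).

.pngEnv <- new.env(parent = emptyenv())

.crcTable <- function() {
  if (is.null(.pngEnv$tab)) {
    poly <- -306674912L  # 0xEDB88320 as signed 32-bit
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L))
             else bitwShiftR(c, 1L)
      }
      tab[n + 1L] <- c
    }
    .pngEnv$tab <- tab
  }
  .pngEnv$tab
}

.crc32 <- function(bytes) {
  tab <- .crcTable()
  c <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    c <- bitwXor(bitwShiftR(c, 8L), tab[bitwAnd(bitwXor(c, b[i]), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

.u32be <- function(x) {
  # x may be a signed 32-bit int (CRC) or a non-negative double (length)
  if (is.integer(x)) {
    as.raw(c(bitwAnd(bitwShiftR(x, 24L), 255L), bitwAnd(bitwShiftR(x, 16L), 255L),
             bitwAnd(bitwShiftR(x, 8L), 255L), bitwAnd(x, 255L)))
  } else {
    as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
  }
}

.readU32be <- function(r) sum(as.integer(r) * c(16777216, 65536, 256, 1))

.pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.u32be(length(data) + 0), body, .u32be(.crc32(body)))
}

#' Write an integer matrix as a PNG file
#'
#' @param m integer matrix. With a palette, values are palette indices;
#'   otherwise 8-bit grayscale values in 0..255.
#' @param path output path.
#' @param palette optional integer matrix (k x 3, RGB 0..255); enables a
#'   paletted (colour type 3) PNG, the format used for label masks.
#' @return invisibly, \code{path}.
#' @export
writePNG <- function(m, path, palette = NULL) {
  h <- nrow(m); w <- ncol(m)
  vals <- as.integer(m)
  colorType <- if (is.null(palette)) 0L else 3L
  if (any(vals < 0L) || any(vals > 255L))
    stopCondition("FormatError", "PNG sample values must be in 0..255")
  if (!is.null(palette) && any(vals >= nrow(palette)))
    stopCondition("FormatError", "palette index out of range")
  # scanlines: filter byte 0 + row bytes (row-major, 8-bit samples)
  raw <- raw((w + 1L) * h)
  idx <- rep(seq_len(h) - 1L, each = w) * (w + 1L) + 1L + rep(seq_len(w), h)
  raw[idx] <- as.raw(t(m))
  z <- memCompress(raw, "gzip")
  ihdr <- c(.u32be(w + 0), .u32be(h + 0),
            as.raw(c(8L, colorType, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           .pngChunk("IHDR", ihdr))
  if (!is.null(palette))
    out <- c(out, .pngChunk("PLTE", as.raw(as.integer(t(palette)))))
  out <- c(out, .pngChunk("IDAT", z), .pngChunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

.unpackBits <- function(bytes, depth, width) {
  if (depth == 8L) return(as.integer(bytes)[seq_len(width)])
  per <- 8L %/% depth
  b <- as.integer(bytes)
  shifts <- seq.int(8L - depth, 0L, by = -depth)
  mask <- bitwShiftL(1L, depth) - 1L
  M <- vapply(shifts, function(s) bitwAnd(bitwShiftR(b, s), mask),
              integer(length(b)))  # bytes x samples-per-byte
  as.vector(t(M))[seq_len(width)]
}

.paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

#' Read a PNG file as an integer matrix
#'
#' Supports non-interlaced grayscale (colour type 0) and paletted (type 3)
#' PNGs at bit depths 1, 2, 4, 8. Paletted files return the palette indices
#' (the label values for masks written by \code{\link{writePNG}}).
#'
#' @param path file path.
#' @return integer matrix (rows = image rows).
#' @export
readPNG <- function(path) {
  if (!file.exists(path))
    stopCondition("FormatError", sprintf("file not found: %s", path))
  r <- readBin(path, "raw", file.info(path)$size)
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(r) < 8 || !identical(r[1:8], sig))
    stopCondition("FormatError", sprintf("not a PNG file: %s", path))
  pos <- 9L
  idat <- list(); ihdr <- NULL
  while (pos + 8L <= length(r)) {
    len <- .readU32be(r[pos:(pos + 3L)])
    type <- rawToChar(r[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) r[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") ihdr <- data
    else if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(ihdr) || !length(idat))
    stopCondition("FormatError", sprintf("corrupt PNG (missing IHDR/IDAT): %s", path))
  w <- .readU32be(ihdr[1:4]); h <- .readU32be(ihdr[5:8])
  depth <- as.integer(ihdr[9]); colorType <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (interlace != 0L)
    stopCondition("FormatError", "interlaced PNG not supported")
  if (!(colorType %in% c(0L, 3L)) || !(depth %in% c(1L, 2L, 4L, 8L)))
    stopCondition("FormatError", sprintf(
      "unsupported PNG (colour type %d, bit depth %d); need grayscale or paletted",
      colorType, depth))
  raw <- memDecompress(do.call(c, idat), "gzip")
  stride <- ceiling(w * depth / 8)
  m <- matrix(0L, nrow = h, ncol = w)
  prev <- integer(stride)
  for (i in seq_len(h)) {
    off <- (i - 1L) * (stride + 1L)
    filt <- as.integer(raw[off + 1L])
    row <- as.integer(raw[(off + 2L):(off + 1L + stride)])
    recon <- switch(as.character(filt),
      "0" = row,
      "1" = Reduce(function(a, b) (a + b) %% 256L, row, accumulate = TRUE),
      "2" = (row + prev) %% 256L,
      "3" = { rc <- integer(stride); a <- 0L
              for (j in seq_len(stride)) {
                rc[j] <- (row[j] + (a + prev[j]) %/% 2L) %% 256L; a <- rc[j] }
              rc },
      "4" = { rc <- integer(stride); a <- 0L; c0 <- 0L
              for (j in seq_len(stride)) {
                rc[j] <- (row[j] + .paeth(a, prev[j], c0)) %% 256L
                a <- rc[j]; c0 <- prev[j] }
              rc },
      stopCondition("FormatError", sprintf("bad PNG filter type %d", filt)))
    prev <- recon
    m[i, ] <- .unpackBits(as.raw(recon), depth, w)
  }
  m
}
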