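# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader/writer for 2-D slices.
# Only what the pipeline needs: one slice per file, integer or float data,
# pixel spacing from pixdim. Written little-endian; reads either endianness.

.niiDatatypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L, 256L, 512L),
  what = c("integer", "integer", "integer", "double", "double", "integer", "integer"),
  size = c(1L, 2L, 4L, 4L, 8L, 1L, 2L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE)

.niiCon <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 2-D slice as a NIfTI-1 file
#'
#' Stores the matrix as a single-slice int16 volume with \code{pixdim}
#' carrying the pixel spacing. Row index maps to the first (fastest-varying)
#' NIfTI dimension.
#'
#' @param m numeric/integer matrix.
#' @param path output path (.nii or .nii.gz).
#' @param pixelSpacing mm per pixel, scalar or (row, col).
#' @return invisibly, \code{path}.
#' @export
writeNifti <- function(m, path, pixelSpacing) {
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  con <- .niiCon(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # data_type..dim_info
  dims <- c(2L, nrow(m), ncol(m), 1L, 1L, 1L, 1L, 1L)
  writeBin(as.integer(dims), con, size = 2)           # dim[8]
  writeBin(raw(14), con)                              # intent_p1..intent_code
  writeBin(4L, con, size = 2)                         # datatype = int16
  writeBin(16L, con, size = 2)                        # bitpix
  writeBin(0L, con, size = 2)                         # slice_start
  writeBin(c(1, pixelSpacing[1], pixelSpacing[2], 1, 0, 0, 0, 0), con, size = 4)  # pixdim[8]
  writeBin(352, con, size = 4)                        # vox_offset (float)
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(raw(2 + 1 + 1 + 4 * 4), con)               # slice_end..toffset
  writeBin(raw(8 + 80 + 24), con)                     # glmax..aux_file
  writeBin(raw(2 + 2 + 6 * 4 + 3 * 16), con)          # qform..srow (all zero)
  writeBin(raw(16), con)                              # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)          # magic
  writeBin(raw(4), con)                               # extension flag
  writeBin(as.integer(round(m)), con, size = 2)       # column-major == dim1 fastest
  invisible(path)
}

#' Read a single-slice NIfTI-1 file
#'
#' @param path .nii or .nii.gz path.
#' @return list with \code{data} (matrix) and \code{pixelSpacing} (row, col)
#'   from the header's pixdim.
#' @export
readNifti <- function(path) {
  if (!file.exists(path))
    stopCondition("FormatError", sprintf("file not found: %s", path))
  con <- .niiCon(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  if (length(hdr) < 348)
    stopCondition("FormatError", sprintf("truncated NIfTI header: %s", path))
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
    if (sz != 348L)
      stopCondition("FormatError", sprintf("not a NIfTI-1 file: %s", path))
  }
  dim8 <- readBin(hdr[41:56], "integer", 8, 2, endian = endian)
  datatype <- readBin(hdr[71:72], "integer", 1, 2, endian = endian)
  pixdim <- readBin(hdr[77:108], "double", 8, 4, endian = endian)
  voxOffset <- readBin(hdr[109:112], "double", 1, 4, endian = endian)
  sclSlope <- readBin(hdr[113:116], "double", 1, 4, endian = endian)
  sclInter <- readBin(hdr[117:120], "double", 1, 4, endian = endian)
  nd <- dim8[1]
  shape <- dim8[1 + seq_len(max(nd, 2))]
  shape[shape == 0L] <- 1L
  if (prod(shape[-(1:2)]) != 1)
    stopCondition("FormatError", sprintf(
      "expected a single 2-D slice, got dims [%s]: %s",
      paste(shape, collapse = "x"), path))
  dt <- .niiDatatypes[.niiDatatypes$code == datatype, ]
  if (nrow(dt) != 1L)
    stopCondition("FormatError", sprintf("unsupported NIfTI datatype %d: %s",
                                         datatype, path))
  n <- shape[1] * shape[2]
  skip <- round(voxOffset) - 352
  if (skip > 0) readBin(con, "raw", skip)
  v <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(v) < n)
    stopCondition("FormatError", sprintf("truncated NIfTI data: %s", path))
  if (sclSlope != 0 && !(sclSlope == 1 && sclInter == 0))
    v <- v * sclSlope + sclInter
  list(data = matrix(v, nrow = shape[1], ncol = shape[2]),
       pixelSpacing = abs(pixdim[2:3]))
}
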