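# Mask and metadata I/O: the package's interface to files on disk.

.maskPalette <- matrix(c(0, 0, 0,        # background
                         220, 80, 80,    # VB
                         80, 200, 80,    # FJ
                         80, 120, 230),  # PA
                       ncol = 3, byrow = TRUE)

#' Read a label mask from PNG or NIfTI
#'
#' PNG files carry no spacing, so \code{pixelSpacing} is required; for NIfTI
#' files the header's pixdim overrides the argument.
#'
#' @param path file path (.png, .nii, .nii.gz).
#' @param pixelSpacing mm per pixel, scalar or (row, col); mandatory for PNG.
#' @return A \linkS4class{LabelMask}.
#' @export
readMask <- function(path, pixelSpacing = NULL) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (is.null(pixelSpacing))
      stopCondition("ArgumentError", "pixelSpacing is required for PNG masks")
    m <- readPNG(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    nii <- readNifti(path)
    m <- round(nii$data)
    pixelSpacing <- nii$pixelSpacing
  } else {
    stopCondition("FormatError", sprintf(
      "unsupported mask format (expect .png/.nii/.nii.gz): %s", path))
  }
  bad <- setdiff(unique(as.vector(m)), 0:3)
  if (length(bad))
    stopCondition("LabelError", sprintf(
      "mask %s contains label value(s) outside {0,1,2,3}: %s",
      path, paste(sort(bad), collapse = ", ")))
  labelMask(m, pixelSpacing)
}

#' Write a label mask to PNG or NIfTI
#'
#' PNG output is 8-bit paletted with labels 0..3 as palette indices; NIfTI
#' output stores the labels as int16 with spacing in the header.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param path output path (.png, .nii, .nii.gz).
#' @return invisibly, \code{path}.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    writePNG(mask@labels, path, palette = .maskPalette)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    writeNifti(mask@labels, path, mask@pixelSpacing)
  } else {
    stopCondition("FormatError", sprintf(
      "unsupported mask format (expect .png/.nii/.nii.gz): %s", path))
  }
  invisible(path)
}

#' Read/write a grayscale slice image as 8-bit PNG
#'
#' Intensities are mapped between [0, 1] doubles and 0..255 PNG samples.
#' @param img numeric matrix in [0, 1].
#' @param path file path.
#' @return \code{writeImage}: invisibly \code{path}; \code{readImage}: a
#'   numeric matrix in [0, 1].
#' @export
writeImage <- function(img, path) {
  v <- pmin(pmax(img, 0), 1)
  writePNG(matrix(as.integer(round(v * 255)), nrow(img), ncol(img)), path)
}

#' @rdname writeImage
#' @export
readImage <- function(path) {
  readPNG(path) / 255
}

#' Load the slice-metadata table
#'
#' The metadata CSV stands in for manual slice preselection: one row per
#' (participant, level) naming the mask (and optionally image) file. Required
#' columns: \code{id}, \code{level}, \code{mask_path}; optional:
#' \code{image_path}, \code{sex}.
#'
#' @param path CSV path.
#' @return data.frame with normalized \code{level} labels.
#' @export
loadMetadata <- function(path) {
  if (!file.exists(path))
    stopCondition("FormatError", sprintf("metadata file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "level", "mask_path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopCondition("SchemaError", sprintf(
      "metadata missing required column(s): %s", paste(miss, collapse = ", ")))
  df$id <- as.character(df$id)
  df$level <- normalizeLevel(df$level)
  if (!is.null(df$sex)) df$sex <- normalizeSex(df$sex)
  key <- paste(df$id, df$level, sep = ":")
  if (anyDuplicated(key))
    stopCondition("DuplicateError", sprintf(
      "duplicate (id, level) pair(s): %s",
      paste(unique(key[duplicated(key)]), collapse = ", ")))
  df
}
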