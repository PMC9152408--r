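# Image and mask I/O. Intensity images live in [0, 1] as numeric
# matrices; integer inputs are scaled by their maximum representable
# value. Masks are 8-bit indexed PNGs with class ids 0..n_classes-1.

#' Read a grayscale image
#'
#' PNG (8/16-bit) and TIFF (integer or 32-bit float) are supported. RGB
#' input is converted to luma (0.2126 R + 0.7152 G + 0.0722 B) with a
#' warning.
#'
#' @param path file path; format chosen by extension.
#' @return numeric matrix, intensities in `[0, 1]` for integer sources.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) .fail("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    .fail("unsupported image format: .", ext))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) {
      warning("RGB input converted to luma")
      x <- 0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
    } else x <- x[, , 1]
  }
  x
}

#' Write a grayscale image
#'
#' `.png` writes 8-bit gray (values clipped to `[0, 1]`); `.tif`/`.tiff`
#' writes 32-bit float, which round-trips exactly and is the format used
#' for intermediate pipeline images.
#'
#' @param image numeric matrix.
#' @param path destination path.
#' @export
write_image <- function(image, path) {
  .check_matrix(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(image, 0), 1), path, dpi = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    .write_float_tiff(image, path)
  } else .fail("unsupported image format: .", ext)
  invisible(path)
}

# Minimal single-strip uncompressed 32-bit-float TIFF writer
# (little-endian). Values outside [0, 1] are stored as-is, which the
# integer-scaled writers cannot do; readTIFF reads the format natively.
.write_float_tiff <- function(image, path) {
  h <- nrow(image); w <- ncol(image)
  con <- file(path, "wb")
  on.exit(close(con))
  data_offset <- 8L
  data_bytes <- 4L * h * w
  ifd_offset <- data_offset + data_bytes
  writeBin(charToRaw("II"), con)                      # little-endian
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_offset, con, size = 4L, endian = "little")
  # pixel data, row-major
  writeBin(as.numeric(t(image)), con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(c(tag, type)), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {        # SHORT: left-justified in the 4-byte slot
      writeBin(as.integer(c(value, 0L)), con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  writeBin(9L, con, size = 2L, endian = "little")     # entry count
  entry(256L, 4L, 1L, w)                              # ImageWidth
  entry(257L, 4L, 1L, h)                              # ImageLength
  entry(258L, 3L, 1L, 32L)                            # BitsPerSample
  entry(259L, 3L, 1L, 1L)                             # no compression
  entry(262L, 3L, 1L, 1L)                             # black-is-zero
  entry(273L, 4L, 1L, data_offset)                    # StripOffsets
  entry(278L, 4L, 1L, h)                              # RowsPerStrip
  entry(279L, 4L, 1L, data_bytes)                     # StripByteCounts
  entry(339L, 3L, 1L, 3L)                             # SampleFormat: float
  writeBin(0L, con, size = 4L, endian = "little")     # no next IFD
  invisible(path)
}

#' Read a label mask (8-bit indexed PNG)
#'
#' @param path PNG path.
#' @return integer matrix of class ids.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) .fail("cannot read mask: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- round(x * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write a label mask (8-bit indexed PNG)
#'
#' Class ids `0..255` are stored as 8-bit gray levels; [read_mask()]
#' recovers them exactly.
#'
#' @param mask integer matrix of class ids.
#' @param path destination PNG path.
#' @export
write_mask <- function(mask, path) {
  if (any(mask < 0L) || any(mask > 255L)) .fail("mask ids must be in 0..255")
  png::writePNG(mask / 255, path)
  invisible(path)
}
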