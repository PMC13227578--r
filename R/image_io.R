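# Grayscale image readers/writers (PNG and TIFF, 8- and 16-bit).

#' Read a grayscale image
#'
#' Reads a PNG or TIFF file into a numeric matrix in \[0, 1\].  Multi-channel
#' files are converted to grayscale by averaging the colour channels (an
#' alpha channel, if present, is dropped).
#'
#' @param path Path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix of intensities in \[0, 1\].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "png") png::readPNG(path)
       else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else stop("unsupported image format: .", ext)
  if (length(dim(x)) == 3L) {
    ch <- min(dim(x)[3], 3L)           # drop alpha
    x <- apply(x[, , seq_len(ch), drop = FALSE], c(1, 2), mean)
  }
  assert_image(x)
  x
}

#' Write a grayscale image
#'
#' Writes a numeric matrix in \[0, 1\] as grayscale PNG (8-bit) or TIFF
#' (8- or 16-bit).  16-bit PNGs can be read but not written.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param path Destination ending in `.png`, `.tif` or `.tiff`.
#' @param bits Bit depth, 8 or 16 (16 requires TIFF).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, bits = 8L) {
  assert_normalized(img)
  if (!bits %in% c(8L, 16L)) stop_invalid("bits must be 8 or 16")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits == 16L) stop_invalid("16-bit output is supported for TIFF only")
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  } else stop("unsupported image format: .", ext)
  invisible(path)
}
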