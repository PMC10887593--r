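#' Read an image file as an 8-bit grayscale intensity matrix
#'
#' PNG files are decoded with the \pkg{png} package; JPEG files require
#' \pkg{EBImage} (listed in Suggests).  Colour images are converted to
#' luminance (0.299 R + 0.587 G + 0.114 B).  Values are returned on the
#' 0--255 scale as doubles.
#'
#' @param path path to a PNG or JPEG file.
#' @return numeric matrix (height x width) with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stopf("reading JPEG requires the EBImage package")
    }
    # EBImage stores images transposed (x, y); bring back to (row, col)
    e <- EBImage::readImage(path)
    a <- EBImage::imageData(e)
    if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  } else {
    stopf("unsupported image format '%s' (PNG or JPEG expected)", ext)
  }
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    img <- if (nc >= 3L) {
      0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      img[, , 1L]
    }
  }
  img * 255
}

#' Write an 8-bit grayscale PNG
#'
#' @param img numeric matrix with values in `[0, 255]`; values are rounded and
#'   clipped to the 8-bit range before writing, so re-reading the file
#'   reproduces `round(img)` exactly.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  if (!is.matrix(img)) stopf("write_gray_png expects a matrix")
  v <- clamp(round(img), 0, 255) / 255
  png::writePNG(v, target = path)
  invisible(path)
}
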