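#' Read a grayscale PNG as a 0-255 intensity matrix
#'
#' Color images are collapsed to intensity by averaging the color channels;
#' an alpha channel, if present, is discarded.
#'
#' @param path Path to a PNG file.
#' @return A numeric matrix with values in \[0, 255\].
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    if (nc >= 3L) {
      a <- (a[, , 1L] + a[, , 2L] + a[, , 3L]) / 3
    } else {
      a <- a[, , 1L]
    }
  }
  a * 255
}

#' Write a 0-255 intensity matrix as an 8-bit grayscale PNG
#'
#' Values are clipped to \[0, 255\] and rounded to integers at write time;
#' all in-memory processing stays in floating point so quantization happens
#' exactly once, at the file boundary.
#'
#' @param img Numeric matrix with values on the 0-255 scale.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  check_gray(img)
  q <- round(clip255(img)) / 255
  png::writePNG(q, target = path)
  invisible(path)
}
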