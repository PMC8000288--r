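#' Image grids
#'
#' Images are plain numeric matrices in row-major visual convention: row 1 is
#' the top image row, column 1 the left edge. Intensities are real-valued
#' during processing and quantized to 8-bit integers in \[0, 255\] only on
#' request (or on PNG export).
#'
#' @name imagegrid
NULL

#' Quantize an image to 8-bit integers
#'
#' Rounds half away from zero, then clips to \[0, 255\]. The explicit
#' tie-break makes quantized pipelines bit-reproducible across platforms.
#'
#' @param img numeric matrix.
#' @return integer-valued numeric matrix in \[0, 255\].
#' @export
#' @examples
#' quantize_image(matrix(c(-3, 0.5, 127.49, 300), 2, 2))
quantize_image <- function(img) {
  stopifnot(is.matrix(img), is.numeric(img))
  q <- sign(img) * floor(abs(img) + 0.5)
  pmin(pmax(q, 0), 255)
}

#' Read an 8-bit grayscale image from PNG
#'
#' Color PNGs are reduced to grayscale by averaging the color channels.
#'
#' @param path file path.
#' @return numeric matrix with values in \[0, 255\].
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3L, dim(x)[3]), drop = FALSE], c(1, 2), mean)
  x * 255
}

#' Write an image as 8-bit grayscale PNG
#'
#' The image is quantized (see [quantize_image()]) before writing.
#'
#' @param img numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(quantize_image(img) / 255, path)
  invisible(path)
}

#' Flip an image horizontally or vertically
#'
#' @param img numeric matrix.
#' @param axis `"horizontal"` mirrors left-right, `"vertical"` top-bottom.
#' @return flipped matrix.
#' @export
flip_image <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") img[, rev(seq_len(ncol(img))), drop = FALSE]
  else img[rev(seq_len(nrow(img))), , drop = FALSE]
}
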