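#' Read a fundus image from a PNG file
#'
#' @param path PNG file path.
#' @return H x W x 3 array (RGB) or H x W matrix (grayscale), values 0--255.
#' @export
read_fundus <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) x <- x[, , 1:3] else x <- x[, , 1]
  }
  round(x * 255)
}

#' Write a fundus image to a PNG file
#'
#' @param img matrix or H x W x 3 array in \[0, 255\].
#' @param path output PNG file path.
#' @return `path`, invisibly.
#' @export
write_fundus <- function(img, path) {
  assert_image(img)
  png::writePNG(clip8(img) / 255, path)
  invisible(path)
}
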