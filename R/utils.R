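# Internal helpers shared across modules. Images are base-R numeric arrays in
# [0, 255]: a matrix H x W for single-channel data, an H x W x 3 array for RGB.
# Pixel coordinates reported to users (circles, crop boxes) are 0-based;
# internal matrix indexing is the usual 1-based R convention.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

is_rgb <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L
is_gray <- function(img) is.matrix(img)

img_h <- function(img) dim(img)[1]
img_w <- function(img) dim(img)[2]

assert_image <- function(img, arg = "image") {
  if (!(is_rgb(img) || is_gray(img)) || any(dim(img)[1:2] < 1))
    stop(sprintf("`%s` must be a non-empty H x W matrix or H x W x 3 array", arg))
  invisible(img)
}

clip8 <- function(x) pmin(pmax(x, 0), 255)

# ITU-R BT.601 luma; used wherever a single-channel view of an RGB image is
# needed (Hough edges, Otsu baseline, non-zero-pixel tests on intensities).
as_gray <- function(img) {
  assert_image(img)
  if (is_gray(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Max over channels: a pixel is "non-zero" if any channel exceeds the
# threshold, so faint colour casts in the background are not missed.
channel_max <- function(img) {
  if (is_gray(img)) return(img)
  pmax(img[, , 1], img[, , 2], img[, , 3])
}

each_channel <- function(img, f) {
  if (is_gray(img)) return(f(img))
  out <- img
  for (ch in 1:3) out[, , ch] <- f(img[, , ch])
  out
}

## ---- EBImage bridge ------------------------------------------------------
# EBImage stores images x-major (width first) in [0, 1]; these wrappers keep
# the rest of the package in row-major [0, 255] arrays.

to_eb <- function(img) {
  if (is_gray(img)) EBImage::Image(t(img) / 255)
  else EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
}

from_eb <- function(eb, rgb) {
  d <- EBImage::imageData(eb)
  if (rgb) aperm(d, c(2, 1, 3)) * 255 else t(d) * 255
}

#' Resize an image with bilinear interpolation
#'
#' @param img matrix or H x W x 3 array, values in \[0, 255\].
#' @param h,w target height and width in pixels.
#' @return resized image of the same kind.
#' @export
resize_image <- function(img, h, w = h) {
  assert_image(img)
  out <- from_eb(EBImage::resize(to_eb(img), w = w, h = h), rgb = is_rgb(img))
  clip8(out)
}

# Rotate about the image centre, bilinear, constant fill; frame size is kept.
rotate_image <- function(img, angle, fill = 0) {
  assert_image(img)
  eb <- EBImage::rotate(to_eb(img), angle, filter = "bilinear",
                        output.dim = c(img_w(img), img_h(img)),
                        bg.col = fill / 255)
  clip8(from_eb(eb, rgb = is_rgb(img)))
}

## ---- Separable Gaussian convolution --------------------------------------
# Borders are extended by mirror reflection (edge pixel repeated), so
# convolving a constant image returns it exactly -- the closed forms of the
# unsharp blend and retinex operators depend on this.

mirror_idx <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

gaussian_kernel1d <- function(sigma, half = ceiling(4 * sigma)) {
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Band matrix form of 1-D convolution: rows select kernel-width windows of
# the padded signal, so each pass is a single dense matrix product.
conv_band <- function(n, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n + 2L * half)
  for (o in 0:(2L * half)) K[cbind(seq_len(n), seq_len(n) + o)] <- kernel[o + 1L]
  K
}

blur_matrix <- function(m, sigma, half = ceiling(4 * sigma)) {
  h <- nrow(m); w <- ncol(m)
  k <- gaussian_kernel1d(sigma, half)
  pr <- mirror_idx(seq(1L - half, h + half), h)
  pc <- mirror_idx(seq(1L - half, w + half), w)
  Kh <- conv_band(h, k)
  Kw <- conv_band(w, k)
  # convolve the deviation from the mean: a constant image is then returned
  # exactly, independent of kernel-normalisation rounding
  mu <- mean(m)
  tmp <- Kh %*% (m - mu)[pr, , drop = FALSE]
  mu + tmp[, pc, drop = FALSE] %*% t(Kw)
}

#' Gaussian blur with reflective borders
#'
#' Separable Gaussian convolution; the kernel half-width is `ceiling(4*sigma)`
#' and borders are mirror-extended, so a constant image is returned unchanged
#' (exactly). Applied per channel on RGB input.
#'
#' @param img image (matrix or H x W x 3 array).
#' @param sigma Gaussian scale in pixels.
#' @return blurred image, same dimensions (not clipped or rounded).
#' @export
gaussian_blur <- function(img, sigma) {
  assert_image(img)
  each_channel(img, function(m) blur_matrix(m, sigma))
}

## ---- Connected components ------------------------------------------------

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L) list(c(0L, 1L), c(1L, 0L))
  else list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
}

#' Label connected components of a binary mask
#'
#' @param mask logical or numeric matrix; non-zero pixels are foreground.
#' @param connectivity 4 or 8 (default 8, suited to thin diagonal structures).
#' @return integer matrix of component labels (0 = background), labelled in
#'   order of first (column-major) occurrence.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  fg <- which(mask != 0)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(fg) == 0L) return(lab)
  h <- nrow(mask); w <- ncol(mask)
  rr <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  id <- integer(length(mask)); id[fg] <- seq_along(fg)
  edges <- integer(0)
  for (off in neighbor_offsets(connectivity)) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    j <- (c2[ok] - 1L) * h + r2[ok]
    hit <- id[j] > 0L
    if (any(hit)) edges <- c(edges, rbind(id[fg[ok][hit]], id[j[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # dense labels in column-major order of first occurrence
  lab[fg] <- match(memb, unique(memb))
  lab
}
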