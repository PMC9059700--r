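# Grad-CAM localization from externally supplied activations and gradients.
# The activation/gradient pair is passed through a backend-agnostic
# interface (plain arrays), so any network framework -- or a hand-built
# fixture -- can feed it.

#' Grad-CAM heat map from last-layer activations and gradients
#'
#' Channel weights are the spatial means of the gradient maps; the raw map
#' is the rectified (negatives clipped to zero) weighted sum of activation
#' channels. The normalized map is the raw map min-max scaled to \[0, 255\]
#' (identically zero when the raw map is constant) and, when `size` is
#' given, bilinearly resized to the original image size. The binary mask is
#' `normalized >= mask_threshold`.
#'
#' @param activations h x w x K array (or h x w matrix for K = 1) of feature
#'   maps from the last convolutional layer.
#' @param gradients array of the same shape: gradients of the class score
#'   with respect to the activations.
#' @param size optional c(H, W) of the input image to resize to.
#' @param mask_threshold threshold on the normalized map (default 100).
#' @return object of class `gradcam_heatmap`: list with `raw`, `normalized`,
#'   `mask`, `mask_threshold`.
#' @export
gradcam <- function(activations, gradients, size = NULL,
                    mask_threshold = 100) {
  if (is.matrix(activations)) activations <- array(activations,
                                                   c(dim(activations), 1))
  if (is.matrix(gradients)) gradients <- array(gradients, c(dim(gradients), 1))
  if (!identical(dim(activations), dim(gradients)))
    stop("activations and gradients must have identical shapes")
  K <- dim(activations)[3]
  if (K == 0) stop("need at least one feature map")
  raw <- matrix(0, dim(activations)[1], dim(activations)[2])
  for (k in seq_len(K))
    raw <- raw + mean(gradients[, , k]) * activations[, , k]
  raw <- pmax(raw, 0)
  rng <- range(raw)
  normalized <- if (diff(rng) < .Machine$double.eps) raw * 0
                else (raw - rng[1]) / diff(rng) * 255
  if (!is.null(size))
    normalized <- clip8(resize_image(normalized, size[1], size[2]))
  structure(list(raw = raw, normalized = normalized,
                 mask = normalized >= mask_threshold,
                 mask_threshold = mask_threshold),
            class = "gradcam_heatmap")
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("Grad-CAM heat map %dx%d, %d mask px at threshold %d\n",
              nrow(x$normalized), ncol(x$normalized), sum(x$mask),
              x$mask_threshold))
  invisible(x)
}

mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
              pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  mask & !interior
}

#' Draw Grad-CAM contours on a fundus image
#'
#' Contours of the heat-map mask are drawn on a copy of the image: green
#' when the prediction score is at least 0.5, red otherwise. The input image
#' is never modified, and the overlay differs from it only on contour
#' pixels.
#'
#' @param image image to annotate (grayscale is promoted to RGB).
#' @param hm a [gradcam_heatmap()] whose normalized map matches the image
#'   size.
#' @param score prediction score in \[0, 1\] deciding the contour colour.
#' @return list with `overlay` (RGB image) and `contours` (list of
#'   data frames of 0-based row/col boundary coordinates, one per connected
#'   mask component).
#' @export
heatmap_to_contours <- function(image, hm, score) {
  stopifnot(inherits(hm, "gradcam_heatmap"))
  if (is_gray(image)) image <- array(rep(image, 3), c(dim(image), 3))
  if (!all(dim(hm$mask) == dim(image)[1:2]))
    stop("heat map size does not match the image")
  colour <- if (score >= 0.5) c(0, 255, 0) else c(255, 0, 0)
  overlay <- image
  contours <- list()
  if (any(hm$mask)) {
    bnd <- mask_boundary(hm$mask)
    lab <- label_components(hm$mask, connectivity = 8L)
    for (comp in seq_len(max(lab))) {
      idx <- which(bnd & lab == comp)
      contours[[comp]] <- data.frame(
        row = ((idx - 1L) %% nrow(bnd)),
        col = ((idx - 1L) %/% nrow(bnd)))
    }
    for (ch in 1:3) {
      pl <- overlay[, , ch]
      pl[bnd] <- colour[ch]
      overlay[, , ch] <- pl
    }
  }
  list(overlay = overlay, contours = contours)
}
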