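# Batch-level augmentation: horizontal/vertical flips and random-angle
# rotation, fully reproducible under a seed. Augmentation is geometric only
# and never alters an image's attached label.

#' Augmentation configuration
#'
#' @param do_hflip,do_vflip,do_rotate which augmented copies to emit.
#' @param rotation_range maximum absolute rotation angle in degrees; angles
#'   are drawn uniformly from `[-rotation_range, rotation_range]`. Must lie
#'   in (-180, 180].
#' @param fill_value background intensity used to fill corners exposed by
#'   rotation (default 0, matching the dark fundus background).
#' @param seed optional integer seed making the drawn angles reproducible.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(do_hflip = TRUE, do_vflip = TRUE, do_rotate = TRUE,
                           rotation_range = 30, fill_value = 0, seed = NULL) {
  stopifnot(rotation_range > -180, rotation_range <= 180)
  structure(list(do_hflip = do_hflip, do_vflip = do_vflip,
                 do_rotate = do_rotate, rotation_range = abs(rotation_range),
                 fill_value = fill_value,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "augment_config")
}

#' Mirror an image along an axis
#'
#' Horizontal flip maps pixel (r, c) to (r, W-1-c); vertical flip maps
#' (r, c) to (H-1-r, c). Flipping twice restores the input exactly.
#'
#' @param image matrix or RGB array.
#' @param axis `"horizontal"` (left-right) or `"vertical"` (top-bottom).
#' @return flipped image.
#' @export
flip_image <- function(image, axis = c("horizontal", "vertical")) {
  assert_image(image)
  axis <- match.arg(axis)
  if (axis == "horizontal") {
    if (is_rgb(image)) image[, rev(seq_len(img_w(image))), , drop = FALSE]
    else image[, rev(seq_len(ncol(image))), drop = FALSE]
  } else {
    if (is_rgb(image)) image[rev(seq_len(img_h(image))), , , drop = FALSE]
    else image[rev(seq_len(nrow(image))), , drop = FALSE]
  }
}

#' Rotate an image by a random angle
#'
#' Bilinear rotation about the image centre by an angle drawn uniformly from
#' `[-rotation_range, rotation_range]`; exposed corners are filled with
#' `fill_value`. With `cfg$seed` set, the drawn angle (and hence the output)
#' is reproducible.
#'
#' @param image matrix or RGB array.
#' @param cfg an [augment_config()].
#' @return list with `image` and the drawn `angle` (degrees).
#' @export
rotate_random <- function(image, cfg = augment_config()) {
  assert_image(image)
  draw <- function() stats::runif(1, -cfg$rotation_range, cfg$rotation_range)
  angle <- if (is.null(cfg$seed)) draw() else with_seed(cfg$seed, draw())
  img <- if (abs(angle) < 1e-12) image
         else rotate_image(image, angle, fill = cfg$fill_value)
  list(image = img, angle = angle)
}

#' Expand an image batch with flips and random rotations
#'
#' For every input image emits the original plus (per config flags) its
#' horizontal flip, vertical flip and one random rotation -- a 4x expansion
#' with the defaults. Any `label` attribute attached to an input image is
#' carried onto its augmented copies unchanged.
#'
#' @param images non-empty list of images.
#' @param cfg an [augment_config()]; `cfg$seed` makes the whole expanded
#'   batch reproducible.
#' @return list of images, `k * length(images)` long, in input order with
#'   each image's copies adjacent.
#' @export
augment_batch <- function(images, cfg = augment_config()) {
  stopifnot(is.list(images), length(images) > 0)
  angles <- if (cfg$do_rotate) {
    draw <- function() stats::runif(length(images),
                                    -cfg$rotation_range, cfg$rotation_range)
    if (is.null(cfg$seed)) draw() else with_seed(cfg$seed, draw())
  } else numeric(0)
  out <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    copies <- list(img)
    if (cfg$do_hflip) copies <- c(copies, list(flip_image(img, "horizontal")))
    if (cfg$do_vflip) copies <- c(copies, list(flip_image(img, "vertical")))
    if (cfg$do_rotate) {
      rot <- if (abs(angles[i]) < 1e-12) img
             else rotate_image(img, angles[i], fill = cfg$fill_value)
      copies <- c(copies, list(rot))
    }
    lab <- attr(img, "label")
    if (!is.null(lab))
      copies <- lapply(copies, function(x) { attr(x, "label") <- lab; x })
    out <- c(out, copies)
  }
  out
}
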