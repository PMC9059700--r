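# Vessel-mask production and post-processing. Segmentation backends are
# pluggable: any function image -> same-size intensity raster qualifies, so
# neural segmenters can be dropped in. The built-in "naive" backend is a
# classical stand-in (CLAHE on the green channel, grayscale black-tophat,
# global threshold), not a trained vessel model.

#' Vessel mask container
#'
#' @param raster single-channel intensity raster (0--255 matrix).
#' @param connectivity pixel connectivity for component analysis (4 or 8;
#'   default 8, which keeps thin diagonal vessel runs connected).
#' @return object of class `vessel_mask`.
#' @export
vessel_mask <- function(raster, connectivity = 8L) {
  stopifnot(is.matrix(raster), connectivity %in% c(4L, 8L))
  structure(list(raster = raster, connectivity = as.integer(connectivity)),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("vessel mask %dx%d, %d non-zero px, %d-connectivity\n",
              nrow(x$raster), ncol(x$raster), sum(x$raster != 0),
              x$connectivity))
  invisible(x)
}

as_vessel_mask <- function(x, connectivity = 8L) {
  if (inherits(x, "vessel_mask")) x else vessel_mask(x, connectivity)
}

# grayscale morphology on a disk structuring element (replicated borders)
disk_offsets <- function(radius) {
  o <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  o[o$dr^2 + o$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
}

morph_extreme <- function(m, radius, fun) {
  h <- nrow(m); w <- ncol(m)
  out <- NULL
  offs <- disk_offsets(radius)
  for (k in seq_len(nrow(offs))) {
    ri <- pmin(pmax(seq_len(h) + offs$dr[k], 1L), h)
    ci <- pmin(pmax(seq_len(w) + offs$dc[k], 1L), w)
    s <- m[ri, ci, drop = FALSE]
    out <- if (is.null(out)) s else fun(out, s)
  }
  out
}

gray_close <- function(m, radius)
  morph_extreme(morph_extreme(m, radius, pmax), radius, pmin)

naive_vessel_backend <- function(image, tophat_radius = 5, threshold = 14) {
  g <- if (is_rgb(image)) extract_channel(image, "G") else image
  ge <- clahe(g)
  bth <- gray_close(ge, tophat_radius) - ge   # dark thin structures
  ifelse(bth > threshold, 255, 0)
}

#' Segment retinal vessels with a pluggable backend
#'
#' @param image fundus image.
#' @param backend `"naive"` for the built-in classical stand-in, or a
#'   function `image -> raster` of identical height/width (e.g. wrapping a
#'   trained segmentation model).
#' @param connectivity component connectivity carried on the returned mask.
#' @return raw (uncleaned) [vessel_mask()].
#' @export
segment_vessels <- function(image, backend = "naive", connectivity = 8L) {
  assert_image(image)
  f <- if (is.function(backend)) backend
       else if (identical(backend, "naive")) naive_vessel_backend
       else stop("backend must be \"naive\" or a function")
  raw <- f(image)
  if (!is.matrix(raw) || !all(dim(raw) == dim(image)[1:2]))
    stop("backend returned a raster of mismatched size")
  vessel_mask(raw, connectivity)
}

#' Clean a vessel mask by intensity and component-size thresholds
#'
#' Pixels below `intensity_threshold` are zeroed first; then every connected
#' component with fewer than `min_component_px` pixels is zeroed (a 100-pixel
#' component survives). The non-zero set only ever shrinks, and the operation
#' is idempotent.
#'
#' @param mask a [vessel_mask()] or intensity matrix.
#' @param intensity_threshold intensities below this are zeroed (default 20).
#' @param min_component_px minimum surviving component size (default 100).
#' @return cleaned [vessel_mask()].
#' @export
clean_mask <- function(mask, intensity_threshold = 20, min_component_px = 100) {
  m <- as_vessel_mask(mask)
  r <- m$raster
  r[r < intensity_threshold] <- 0
  lab <- label_components(r != 0, connectivity = m$connectivity)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    r[lab > 0 & sizes[pmax(lab, 1L)] < min_component_px] <- 0
  }
  vessel_mask(r, m$connectivity)
}

#' Inpaint vessel pixels with a diffusion fill
#'
#' Replaces masked pixels by the harmonic (Laplace) interpolant of the
#' surrounding unmasked values, iterated to convergence with a Jacobi
#' scheme -- a classical diffusion-based fill. Pixels outside the mask are
#' returned untouched.
#'
#' @param image fundus image (matrix or RGB array).
#' @param mask a [vessel_mask()] or matrix; non-zero pixels are filled.
#' @param tol maximum per-iteration change (intensity units) at convergence.
#' @param max_iter iteration cap.
#' @return image with masked pixels filled.
#' @export
inpaint_vessels <- function(image, mask, tol = 0.05, max_iter = 500) {
  assert_image(image)
  m <- as_vessel_mask(mask)$raster != 0
  if (!any(m)) return(image)
  if (all(m)) stop("mask covers the entire image; nothing to diffuse from")
  if (!all(dim(m) == dim(image)[1:2])) stop("mask size mismatch")
  h <- nrow(m); w <- ncol(m)
  up <- c(1L, seq_len(h - 1L)); dn <- c(seq_len(h - 1L) + 1L, h)
  lf <- c(1L, seq_len(w - 1L)); rt <- c(seq_len(w - 1L) + 1L, w)
  fill <- function(orig) {
    x <- orig
    x[m] <- mean(x[!m])
    for (it in seq_len(max_iter)) {
      avg <- (x[up, ] + x[dn, ] + x[, lf] + x[, rt]) / 4
      delta <- max(abs(avg[m] - x[m]))
      x[m] <- avg[m]
      if (delta < tol) break
    }
    orig[m] <- round(x[m])   # pixels outside the mask stay untouched
    orig
  }
  each_channel(image, fill)
}
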