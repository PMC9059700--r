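# Image-enhancement operators. All operate on 0--255 arrays and preserve
# dimensions; RGB inputs are processed per channel.

#' CLAHE configuration
#'
#' @param clip_limit contrast factor limiting the per-tile histogram slope
#'   (default 2); the per-tile bin cap is `clip_limit * tile_pixels / levels`
#'   and clipped excess is redistributed uniformly. `Inf` disables clipping
#'   (plain per-tile equalization).
#' @param tile_grid c(rows, cols) of the tile grid (default 5 x 5).
#' @param levels number of gray levels L (default 256). Inputs are assumed
#'   integer-valued in \[0, L-1\].
#' @return object of class `clahe_config`.
#' @export
clahe_config <- function(clip_limit = 2, tile_grid = c(5, 5), levels = 256) {
  stopifnot(clip_limit > 0, length(tile_grid) == 2, all(tile_grid >= 1),
            levels >= 2)
  structure(list(clip_limit = clip_limit, tile_grid = as.integer(tile_grid),
                 levels = as.integer(levels)), class = "clahe_config")
}

#' Gaussian unsharp-blend configuration
#'
#' The enhanced image is `alpha * I + beta * (G_sigma * I) + gamma`, clipped
#' to \[0, 255\]. With the default `alpha = 4, beta = -4, sigma = 10,
#' gamma = 128` a constant image maps exactly to 128 (since
#' `alpha + beta = 0`), and local deviations from the blurred surround are
#' amplified fourfold around that midpoint.
#'
#' @param alpha weight of the original image.
#' @param beta weight of the Gaussian-blurred image.
#' @param sigma Gaussian scale in pixels.
#' @param gamma additive offset.
#' @return object of class `gaussian_blend_config`.
#' @export
gaussian_blend_config <- function(alpha = 4, beta = -4, sigma = 10,
                                  gamma = 128) {
  structure(list(alpha = alpha, beta = beta, sigma = sigma, gamma = gamma),
            class = "gaussian_blend_config")
}

#' Multiscale retinex configuration
#'
#' @param scales Gaussian surround scales (default `c(5, 35, 150)`).
#' @param weights per-scale weights, summing to 1 (default equal thirds).
#' @param epsilon positive offset added before taking logs (default 1, the
#'   8-bit convention avoiding log 0).
#' @return object of class `msr_config`.
#' @export
msr_config <- function(scales = c(5, 35, 150),
                       weights = rep(1 / length(scales), length(scales)),
                       epsilon = 1) {
  stopifnot(length(scales) == length(weights), epsilon > 0,
            abs(sum(weights) - 1) < 1e-8)
  structure(list(scales = scales, weights = weights, epsilon = epsilon),
            class = "msr_config")
}

#' Extract a colour channel
#'
#' The green plane carries the best vessel/exudate/haemorrhage contrast in
#' fundus photographs and is the usual single-channel choice.
#'
#' @param image H x W x 3 RGB array.
#' @param channel one of "R", "G", "B".
#' @return H x W matrix with the selected plane, values unchanged.
#' @export
extract_channel <- function(image, channel = c("G", "R", "B")) {
  channel <- match.arg(channel)
  if (!is_rgb(image)) stop("extract_channel requires an RGB image")
  image[, , match(channel, c("R", "G", "B"))]
}

# per-tile clipped-equalization lookup tables: rows = tiles (row-major grid),
# cols = gray levels
clahe_tile_maps <- function(m, cfg) {
  L <- cfg$levels
  gy <- cfg$tile_grid[1]; gx <- cfg$tile_grid[2]
  h <- nrow(m); w <- ncol(m)
  rb <- floor(seq(0, h, length.out = gy + 1))
  cb <- floor(seq(0, w, length.out = gx + 1))
  maps <- matrix(0, gy * gx, L)
  for (ty in seq_len(gy)) for (tx in seq_len(gx)) {
    tile <- m[(rb[ty] + 1):rb[ty + 1], (cb[tx] + 1):cb[tx + 1]]
    n <- length(tile)
    hist <- tabulate(pmin(pmax(round(tile), 0), L - 1) + 1L, nbins = L)
    if (is.finite(cfg$clip_limit)) {
      cap <- cfg$clip_limit * n / L
      clipped <- pmin(hist, cap)
      hist <- clipped + (n - sum(clipped)) / L   # uniform redistribution
    }
    # inclusive CDF of normalized counts, mapped to [0, L-1] with floor
    maps[(ty - 1) * gx + tx, ] <- floor((L - 1) * cumsum(hist) / n)
  }
  list(maps = maps, rb = rb, cb = cb, gy = gy, gx = gx)
}

clahe_channel <- function(m, cfg) {
  L <- cfg$levels
  tm <- clahe_tile_maps(m, cfg)
  gy <- tm$gy; gx <- tm$gx
  h <- nrow(m); w <- ncol(m)
  v <- pmin(pmax(round(m), 0), L - 1)
  if (gy == 1L && gx == 1L)
    return(matrix(tm$maps[1, v + 1L], h, w))
  # bilinear interpolation between the four surrounding tile mappings
  tcy <- (tm$rb[-1] + tm$rb[-(gy + 1)]) / 2 - 0.5   # tile centres, 0-based
  tcx <- (tm$cb[-1] + tm$cb[-(gx + 1)]) / 2 - 0.5
  py <- findInterval(seq_len(h) - 1, tcy)           # lower tile index, 0..gy
  px <- findInterval(seq_len(w) - 1, tcx)
  y0 <- pmax(py, 1L); y1 <- pmin(py + 1L, gy)
  x0 <- pmax(px, 1L); x1 <- pmin(px + 1L, gx)
  fy <- ifelse(y1 == y0, 0, ((seq_len(h) - 1) - tcy[y0]) / (tcy[y1] - tcy[y0]))
  fx <- ifelse(x1 == x0, 0, ((seq_len(w) - 1) - tcx[x0]) / (tcx[x1] - tcx[x0]))
  fy <- pmin(pmax(fy, 0), 1); fx <- pmin(pmax(fx, 0), 1)
  Y0 <- matrix(y0, h, w); Y1 <- matrix(y1, h, w)
  X0 <- matrix(x0, h, w, byrow = TRUE); X1 <- matrix(x1, h, w, byrow = TRUE)
  FY <- matrix(fy, h, w); FX <- matrix(fx, h, w, byrow = TRUE)
  look <- function(Y, X)
    matrix(tm$maps[cbind(as.vector((Y - 1) * gx + X), as.vector(v) + 1L)], h, w)
  out <- (1 - FY) * (1 - FX) * look(Y0, X0) + (1 - FY) * FX * look(Y0, X1) +
         FY * (1 - FX) * look(Y1, X0) + FY * FX * look(Y1, X1)
  round(out)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Per-tile histogram equalization: each tile's intensity histogram is
#' clipped at `clip_limit * tile_pixels / levels` (excess redistributed
#' uniformly), the clipped inclusive CDF maps level `v` to
#' `floor((L-1) * CDF(v))`, and per-pixel outputs are bilinearly interpolated
#' between the four neighbouring tile mappings. A flat tile maps to a flat
#' output, and each tile mapping is monotone in the input level.
#'
#' @param image matrix or RGB array (RGB is equalized per channel).
#' @param cfg a [clahe_config()].
#' @return image of the same kind, integer values in \[0, levels-1\].
#' @export
clahe <- function(image, cfg = clahe_config()) {
  assert_image(image)
  each_channel(image, function(m) clahe_channel(m, cfg))
}

#' Gaussian unsharp blend
#'
#' @param image matrix or RGB array.
#' @param cfg a [gaussian_blend_config()].
#' @return enhanced image, clipped to \[0, 255\] and rounded.
#' @export
gaussian_blend <- function(image, cfg = gaussian_blend_config()) {
  assert_image(image)
  each_channel(image, function(m)
    round(clip8(cfg$alpha * m + cfg$beta * blur_matrix(m, cfg$sigma) + cfg$gamma)))
}

#' Multiscale retinex
#'
#' Computes the raw retinex map, the weighted sum over scales of
#' `log(I + eps) - log(G_sigma_n * I + eps)`, then min-max rescales it to
#' \[0, 255\] (a constant raw map -- e.g. from constant input -- is defined
#' as all zeros). Applied per channel on RGB input.
#'
#' @param image matrix or RGB array.
#' @param cfg an [msr_config()].
#' @param rescale if `FALSE`, return the raw (unscaled) retinex map.
#' @return image of the same kind.
#' @export
msr <- function(image, cfg = msr_config(), rescale = TRUE) {
  assert_image(image)
  each_channel(image, function(m) {
    raw <- 0
    for (k in seq_along(cfg$scales))
      raw <- raw + cfg$weights[k] *
        (log(m + cfg$epsilon) - log(blur_matrix(m, cfg$scales[k]) + cfg$epsilon))
    if (!rescale) return(raw)
    rng <- range(raw)
    if (diff(rng) < .Machine$double.eps * 255) return(raw * 0)
    round((raw - rng[1]) / diff(rng) * 255)
  })
}

#' Apply a named preprocessing variant
#'
#' Composes RoI cropping with the named operator chain used in the
#' preprocessing benchmark: `original` (resize only), `cropped`, `green`,
#' `green_clahe`, `green_gaussian`, `rgb_clahe`, `rgb_gaussian`, `msr`,
#' `vessel_seg` (cleaned naive vessel mask as the image), `vessel_inpaint`.
#'
#' @param image RGB fundus image.
#' @param variant variant name (see above).
#' @param params [hough_params()] used for cropping.
#' @param out_size working resolution (default 256).
#' @return processed image (matrix for single-channel variants, RGB array
#'   otherwise).
#' @export
apply_variant <- function(image, variant, params = hough_params(),
                          out_size = 256) {
  variants <- c("original", "cropped", "green", "green_clahe",
                "green_gaussian", "rgb_clahe", "rgb_gaussian", "msr",
                "vessel_seg", "vessel_inpaint")
  if (!variant %in% variants)
    stop("unknown variant '", variant, "'; expected one of: ",
         paste(variants, collapse = ", "))
  if (variant == "original") return(resize_image(image, out_size))
  cr <- crop_roi(image, params, out_size)$image
  switch(variant,
    cropped        = cr,
    green          = extract_channel(cr, "G"),
    green_clahe    = clahe(extract_channel(cr, "G")),
    green_gaussian = gaussian_blend(extract_channel(cr, "G")),
    rgb_clahe      = clahe(cr),
    rgb_gaussian   = gaussian_blend(cr),
    msr            = msr(cr),
    vessel_seg     = clean_mask(segment_vessels(cr))$raster,
    vessel_inpaint = inpaint_vessels(cr, clean_mask(segment_vessels(cr)))
  )
}
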