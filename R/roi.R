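# Automatic foreground cropping. The circular fundus disc is located with a
# gradient circular Hough transform: Sobel edge pixels vote for candidate
# centres along their gradient direction over the admissible radius range;
# peak centres are kept with non-maximum suppression, and each centre's
# radius is the most supported edge distance. Among the ranked candidates,
# the chosen circle is the first whose bounding box (plus a small margin)
# contains every non-zero pixel -- so only background is cropped away.

#' Parameters of the gradient Hough circle detector
#'
#' Defaults follow the validated settings for 8-bit fundus photographs:
#' accumulator at image resolution, centres at least 20 px apart,
#' accumulator threshold 30, gradient (edge) threshold 50, radii between a
#' quarter of the smaller image side and the larger side.
#'
#' @param dp_inverse_ratio inverse ratio of accumulator to image resolution
#'   (1 = full resolution).
#' @param min_center_distance minimum distance between detected centres (px).
#' @param accumulator_threshold minimum centre votes for a candidate.
#' @param gradient_threshold minimum Sobel gradient magnitude for a pixel to
#'   be treated as an edge.
#' @param min_radius,max_radius radius search range in px; defaults
#'   `floor(min(H, W) / 4)` and `max(H, W)` (resolved against the image).
#' @param outside_margin rows/cols by which the candidate's bounding box is
#'   expanded when testing that no non-zero pixel is left outside.
#' @param nonzero_threshold intensity above which a pixel counts as non-zero
#'   (0 = strictly non-zero; raise to ~10 for JPEG compression noise).
#' @return object of class `hough_params`.
#' @export
hough_params <- function(dp_inverse_ratio = 1, min_center_distance = 20,
                         accumulator_threshold = 30, gradient_threshold = 50,
                         min_radius = NULL, max_radius = NULL,
                         outside_margin = 5, nonzero_threshold = 0) {
  stopifnot(dp_inverse_ratio > 0, min_center_distance > 0,
            accumulator_threshold > 0, gradient_threshold > 0,
            outside_margin >= 0, nonzero_threshold >= 0)
  structure(list(
    dp_inverse_ratio = dp_inverse_ratio,
    min_center_distance = min_center_distance,
    accumulator_threshold = accumulator_threshold,
    gradient_threshold = gradient_threshold,
    min_radius = min_radius, max_radius = max_radius,
    outside_margin = outside_margin, nonzero_threshold = nonzero_threshold
  ), class = "hough_params")
}

resolve_radii <- function(params, H, W) {
  rmin <- if (is.null(params$min_radius)) floor(min(H, W) / 4) else params$min_radius
  rmax <- if (is.null(params$max_radius)) max(H, W) else params$max_radius
  if (rmin >= rmax) stop("min_radius must be smaller than max_radius")
  c(rmin, rmax)
}

sobel_gradients <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  pr <- c(1, seq_len(h), h)          # replicate borders
  pc <- c(1, seq_len(w), w)
  p <- gray[pr, pc]
  i <- 2:(h + 1); j <- 2:(w + 1)
  gx <- (p[i - 1, j + 1] + 2 * p[i, j + 1] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i, j - 1] + p[i + 1, j - 1])
  gy <- (p[i + 1, j - 1] + 2 * p[i + 1, j] + p[i + 1, j + 1]) -
        (p[i - 1, j - 1] + 2 * p[i - 1, j] + p[i - 1, j + 1])
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Detect circle candidates with the gradient Hough transform
#'
#' @param image fundus image (RGB array or grayscale matrix, 0--255).
#' @param params a [hough_params()].
#' @return data frame of candidates sorted by accumulator score (columns
#'   `row`, `col` -- 0-based centre -- `radius`, `score`); zero rows when no
#'   circle reaches the accumulator threshold.
#' @export
detect_circles <- function(image, params = hough_params()) {
  assert_image(image)
  gray <- as_gray(image)
  H <- nrow(gray); W <- ncol(gray)
  rad <- resolve_radii(params, H, W)
  g <- sobel_gradients(gray)
  edge <- which(g$mag >= params$gradient_threshold)
  if (length(edge) == 0L) return(empty_candidates())

  er <- ((edge - 1L) %% H) + 1L
  ec <- ((edge - 1L) %/% H) + 1L
  ur <- g$gy[edge] / g$mag[edge]
  uc <- g$gx[edge] / g$mag[edge]

  step <- max(1, round(params$dp_inverse_ratio))
  radii <- seq(rad[1], min(rad[2], ceiling(sqrt(H^2 + W^2))), by = step)
  # every edge pixel votes along +/- its gradient direction at each radius;
  # one pass builds all vote indices, a single tabulate() accumulates them
  acc <- numeric(H * W)
  chunk <- max(1L, floor(4e6 / max(1L, length(edge))))
  for (i0 in seq(1L, length(radii), by = chunk)) {
    rs <- radii[i0:min(length(radii), i0 + chunk - 1L)]
    tr <- rep(rs, each = length(edge))
    vr <- round(c(er + tr * ur, er - tr * ur))
    vc <- round(c(ec + tr * uc, ec - tr * uc))
    ok <- vr >= 1L & vr <= H & vc >= 1L & vc <= W
    if (!any(ok)) next
    acc <- acc + tabulate((vc[ok] - 1L) * H + vr[ok], nbins = H * W)
  }
  if (max(acc) == 0) return(empty_candidates())
  accm <- matrix(acc, H, W)

  # 3x3 local maxima above the accumulator threshold
  pk <- which(accm >= params$accumulator_threshold)
  if (length(pk) == 0L) return(empty_candidates())
  if (length(pk) > 2000L)
    pk <- pk[order(accm[pk], decreasing = TRUE)[1:2000]]
  pr <- ((pk - 1L) %% H) + 1L
  pc <- ((pk - 1L) %/% H) + 1L
  is_max <- vapply(seq_along(pk), function(k) {
    r0 <- max(1L, pr[k] - 1L):min(H, pr[k] + 1L)
    c0 <- max(1L, pc[k] - 1L):min(W, pc[k] + 1L)
    accm[pk[k]] >= max(accm[r0, c0])
  }, logical(1))
  pk <- pk[is_max]; pr <- pr[is_max]; pc <- pc[is_max]
  ord <- order(accm[pk], decreasing = TRUE)
  pk <- pk[ord]; pr <- pr[ord]; pc <- pc[ord]

  # greedy non-maximum suppression on centre distance
  keep <- integer(0)
  for (k in seq_along(pk)) {
    if (length(keep) == 0L ||
        all(sqrt((pr[keep] - pr[k])^2 + (pc[keep] - pc[k])^2) >=
            params$min_center_distance))
      keep <- c(keep, k)
    if (length(keep) >= 24L) break
  }
  pr <- pr[keep]; pc <- pc[keep]; pk <- pk[keep]

  # sub-pixel centres: accumulator-weighted centroid in a 5x5 window
  prf <- numeric(length(pk)); pcf <- numeric(length(pk))
  for (k in seq_along(pk)) {
    r0 <- max(1L, pr[k] - 2L):min(H, pr[k] + 2L)
    c0 <- max(1L, pc[k] - 2L):min(W, pc[k] + 2L)
    wts <- accm[r0, c0, drop = FALSE]
    prf[k] <- sum(r0 * rowSums(wts)) / sum(wts)
    pcf[k] <- sum(c0 * colSums(wts)) / sum(wts)
  }

  # radius per centre: most supported edge distance within range, refined
  # to sub-pixel by averaging the distances near the winning bin
  cand <- lapply(seq_along(pk), function(k) {
    d <- sqrt((er - prf[k])^2 + (ec - pcf[k])^2)
    d <- d[d >= rad[1] - 0.5 & d <= rad[2] + 0.5]
    if (length(d) == 0L) return(NULL)
    db <- round(d)
    tb <- tabulate(db - rad[1] + 1L, nbins = rad[2] - rad[1] + 1L)
    peak <- rad[1] + which.max(tb) - 1L
    data.frame(row = prf[k] - 1, col = pcf[k] - 1,
               radius = mean(d[abs(d - peak) <= 2]),
               score = accm[pk[k]])
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand)) return(empty_candidates())
  cand <- cand[order(cand$score, decreasing = TRUE), , drop = FALSE]
  # re-suppress: sub-pixel refinement may have drawn two centres together
  keep <- integer(0)
  for (k in seq_len(nrow(cand))) {
    if (length(keep) == 0L ||
        all(sqrt((cand$row[keep] - cand$row[k])^2 +
                 (cand$col[keep] - cand$col[k])^2) >=
            params$min_center_distance))
      keep <- c(keep, k)
  }
  cand[keep, , drop = FALSE]
}

empty_candidates <- function()
  data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
             score = numeric(0))

circle_box <- function(row, col, radius, H, W) {
  # 0-based half-open, clamped to the frame
  c(row_lo = max(0, floor(row - radius)),
    row_hi = min(H, ceiling(row + radius) + 1),
    col_lo = max(0, floor(col - radius)),
    col_hi = min(W, ceiling(col + radius) + 1))
}

crop_box <- function(row_lo, row_hi, col_lo, col_hi, method,
                     chosen_circle = NULL) {
  structure(list(row_lo = row_lo, row_hi = row_hi, col_lo = col_lo,
                 col_hi = col_hi, method = method,
                 chosen_circle = chosen_circle), class = "crop_box")
}

#' @export
print.crop_box <- function(x, ...) {
  cat(sprintf("crop box rows [%d, %d), cols [%d, %d), method=%s\n",
              x$row_lo, x$row_hi, x$col_lo, x$col_hi, x$method))
  invisible(x)
}

count_outside <- function(nz_rows, nz_cols, box, margin) {
  sum(nz_rows < box["row_lo"] - margin | nz_rows >= box["row_hi"] + margin |
      nz_cols < box["col_lo"] - margin | nz_cols >= box["col_hi"] + margin)
}

#' Choose the fundus circle among Hough candidates
#'
#' Returns the highest-scoring candidate whose clamped bounding box, expanded
#' by `outside_margin` rows/columns, contains every pixel brighter than
#' `nonzero_threshold`; if none qualifies, the candidate excluding the fewest
#' non-zero pixels wins (ties broken toward the larger radius, so foreground
#' is preferentially preserved).
#'
#' @param image the fundus image the candidates were detected on.
#' @param candidates candidate data frame from [detect_circles()].
#' @param params a [hough_params()].
#' @return single-row data frame (row, col, radius, score).
#' @export
select_fundus_circle <- function(image, candidates, params = hough_params()) {
  assert_image(image)
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("no circle candidates to select from")
  H <- img_h(image); W <- img_w(image)
  nz <- which(channel_max(image) > params$nonzero_threshold)
  nz_rows <- ((nz - 1L) %% H)        # 0-based
  nz_cols <- ((nz - 1L) %/% H)
  outside <- vapply(seq_len(nrow(candidates)), function(k) {
    box <- circle_box(candidates$row[k], candidates$col[k],
                      candidates$radius[k], H, W)
    count_outside(nz_rows, nz_cols, box, params$outside_margin)
  }, numeric(1))
  pass <- which(outside == 0)
  if (length(pass)) return(candidates[pass[1], , drop = FALSE])
  best <- which(outside == min(outside))
  best <- best[order(candidates$radius[best], decreasing = TRUE)][1]
  candidates[best, , drop = FALSE]
}

#' Crop the fundus region of interest
#'
#' Detects the fundus disc with the gradient Hough transform, forms the
#' bounding box of the selected circle (clamped to the frame), crops, and
#' resizes to `out_size` x `out_size`. When no circle is found the fallback
#' is the tight bounding box of all non-zero pixels (the whole frame for an
#' empty image), flagged in the returned box's `method`.
#'
#' @param image 8-bit RGB fundus image (grayscale also accepted).
#' @param params a [hough_params()].
#' @param out_size output side length in pixels (default 256).
#' @return list with `image` (cropped and resized) and `box` (a `crop_box`
#'   with 0-based half-open bounds, the chosen circle and the method used:
#'   `hough` or `fallback`).
#' @export
crop_roi <- function(image, params = hough_params(), out_size = 256) {
  assert_image(image)
  H <- img_h(image); W <- img_w(image)
  cand <- detect_circles(image, params)
  if (nrow(cand) > 0L) {
    ch <- select_fundus_circle(image, cand, params)
    b <- circle_box(ch$row, ch$col, ch$radius, H, W)
    box <- crop_box(b["row_lo"], b["row_hi"], b["col_lo"], b["col_hi"],
                    method = "hough", chosen_circle = ch)
  } else {
    box <- fallback_box(image, params)
  }
  cropped <- crop_to_box(image, box)
  list(image = resize_image(cropped, out_size, out_size), box = box)
}

fallback_box <- function(image, params) {
  H <- img_h(image); W <- img_w(image)
  nz <- which(channel_max(image) > params$nonzero_threshold)
  if (length(nz) == 0L)
    return(crop_box(0, H, 0, W, method = "fallback"))
  r <- ((nz - 1L) %% H); c <- ((nz - 1L) %/% H)
  crop_box(min(r), max(r) + 1, min(c), max(c) + 1, method = "fallback")
}

crop_to_box <- function(image, box) {
  ri <- (box$row_lo + 1):box$row_hi
  ci <- (box$col_lo + 1):box$col_hi
  if (is_rgb(image)) image[ri, ci, , drop = FALSE] else image[ri, ci, drop = FALSE]
}

#' Otsu largest-contour crop (baseline)
#'
#' Baseline foreground cropping: Otsu-threshold the grayscale image, keep the
#' largest connected foreground component, and crop to its bounding box
#' (resized to `out_size`). On dark images whose disc intensity sits close to
#' the background this baseline is known to clip the disc; the Hough-based
#' [crop_roi()] is the recommended method.
#'
#' @inheritParams crop_roi
#' @return list with `image` and `box` (`method = "otsu"`, or `"fallback"`
#'   whole-frame when thresholding yields no foreground).
#' @export
otsu_contour_crop <- function(image, out_size = 256) {
  assert_image(image)
  H <- img_h(image); W <- img_w(image)
  gray <- as_gray(image)
  thr <- EBImage::otsu(EBImage::Image(t(gray) / 255), range = c(0, 1)) * 255
  fg <- gray > thr
  if (!any(fg)) {
    box <- crop_box(0, H, 0, W, method = "fallback")
  } else {
    lab <- label_components(fg, connectivity = 8L)
    big <- which.max(tabulate(lab[lab > 0]))
    idx <- which(lab == big)
    r <- ((idx - 1L) %% H); c <- ((idx - 1L) %/% H)
    box <- crop_box(min(r), max(r) + 1, min(c), max(c) + 1, method = "otsu")
  }
  cropped <- crop_to_box(image, box)
  list(image = resize_image(cropped, out_size, out_size), box = box)
}
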