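# Seedable synthetic fundus generator. Images emulate the geometry that the
# preprocessing pipeline exploits: a bright, possibly clipped circular fundus
# disc on a near-black background (< 20 everywhere outside the disc and its
# one-pixel anti-alias ring), branching dark vessels rooted at an optic-disc
# region, and per-disease lesion stamps. Every image carries exact ground
# truth (disc circle, vessel mask, lesion coordinates, 8-bit label vector).

# lesion tag -> disease class (order N, D, G, C, A, H, M, O)
lesion_tag_classes <- c(
  exudate = "D", hemorrhage = "D", microaneurysm = "D",
  cup = "G", haze = "C", drusen = "A", flame = "H",
  crescent = "M", patch = "O"
)

# diagnostic keyword emitted per condition (shared with the relabeler's
# default map; configurable there)
synth_keywords <- c(
  N = "normal fundus",
  D = "moderate non proliferative retinopathy",
  G = "glaucoma",
  C = "cataract",
  A = "dry age-related macular degeneration",
  H = "hypertensive retinopathy",
  M = "pathological myopia",
  O = "macular epiretinal membrane"
)

# lesion budget per condition used by generate_dataset()
condition_lesions <- list(
  N = list(),
  D = list(exudate = 4, hemorrhage = 3, microaneurysm = 6),
  G = list(cup = 1),
  C = list(haze = 1),
  A = list(drusen = 7),
  H = list(flame = 5),
  M = list(crescent = 1),
  O = list(patch = 2)
)

#' Specification of one synthetic fundus image
#'
#' @param image_size integer (square) or length-2 c(H, W) in pixels.
#' @param disc_center numeric c(row, col), 0-based; default frame centre.
#' @param disc_radius disc radius in pixels; must be at least
#'   `min(image_size) / 8`. Default `0.42 * min(image_size)`.
#' @param clip_fraction maximum fraction of the disc area allowed outside the
#'   frame, in \[0, 0.3\]; used by [random_synth_spec()] when placing discs.
#' @param n_vessels number of vessel random walks rooted at the optic disc.
#' @param lesion_counts named list, lesion tag -> count. Tags:
#'   `r paste(names(lesion_tag_classes), collapse = ", ")`.
#' @param illumination_gradient relative left-right shading slope across the
#'   disc (0 = flat illumination).
#' @param noise_sd Gaussian pixel-noise standard deviation (intensity units);
#'   background noise is truncated below 20 so the dark-background invariant
#'   holds.
#' @param seed integer RNG seed; a fixed seed makes the output byte-identical
#'   across runs.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(image_size = c(256, 256), disc_center = NULL,
                       disc_radius = NULL, clip_fraction = 0,
                       n_vessels = 6, lesion_counts = list(),
                       illumination_gradient = 0.15, noise_sd = 2,
                       seed = 1L) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  if (is.null(disc_radius)) disc_radius <- round(0.42 * min(H, W))
  if (disc_radius < min(H, W) / 8)
    stop("disc_radius must be at least image_size/8")
  if (clip_fraction < 0 || clip_fraction > 0.3)
    stop("clip_fraction must lie in [0, 0.3]")
  if (is.null(disc_center)) disc_center <- c((H - 1) / 2, (W - 1) / 2)
  bad <- names(lesion_counts)[!names(lesion_counts) %in% names(lesion_tag_classes)]
  if (length(bad)) stop("unknown lesion tags: ", paste(bad, collapse = ", "))
  structure(list(
    image_size = c(H, W), disc_center = as.numeric(disc_center),
    disc_radius = as.numeric(disc_radius), clip_fraction = clip_fraction,
    n_vessels = as.integer(n_vessels), lesion_counts = lesion_counts,
    illumination_gradient = illumination_gradient, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

# distance from disc centre to the nearest frame point; > R means the disc
# lies entirely outside the frame
dist_center_to_frame <- function(center, H, W) {
  dr <- pmax(0, pmax(-center[1], center[1] - (H - 1)))
  dc <- pmax(0, pmax(-center[2], center[2] - (W - 1)))
  sqrt(dr^2 + dc^2)
}

# fraction of circle area cut off by a chord at distance t from the centre
chord_fraction <- function(t, R) {
  u <- pmin(1, pmax(-1, t / R))
  (acos(u) - u * sqrt(1 - u^2)) / pi
}

#' Draw a randomised synthetic fundus specification
#'
#' Radius and centre are randomised; with `clip_fraction > 0` the disc is
#' pushed toward a random frame edge so that up to that fraction of its area
#' falls outside the frame.
#'
#' @inheritParams synth_spec
#' @param seed integer seed controlling the randomised geometry (also stored
#'   as the rendering seed).
#' @return a `synth_spec`.
#' @export
random_synth_spec <- function(seed, image_size = c(256, 256),
                              clip_fraction = 0, n_vessels = 6,
                              lesion_counts = list(), noise_sd = 2) {
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  H <- image_size[1]; W <- image_size[2]
  with_seed(seed, {
    R <- round(stats::runif(1, 0.30, 0.44) * min(H, W))
    f <- stats::runif(1, 0, clip_fraction)
    if (f < 0.01) {
      ctr <- c(stats::runif(1, R + 1, H - R - 2), stats::runif(1, R + 1, W - R - 2))
    } else {
      # edge distance t with chord_fraction(t) = f, disc pushed over one edge
      t <- stats::uniroot(function(t) chord_fraction(t, R) - f, c(0, R))$root
      side <- sample(4L, 1L)
      ctr <- c(stats::runif(1, R + 1, H - R - 2), stats::runif(1, R + 1, W - R - 2))
      if (side == 1L) ctr[2] <- t
      if (side == 2L) ctr[2] <- (W - 1) - t
      if (side == 3L) ctr[1] <- t
      if (side == 4L) ctr[1] <- (H - 1) - t
    }
    synth_spec(image_size = image_size, disc_center = ctr, disc_radius = R,
               clip_fraction = clip_fraction, n_vessels = n_vessels,
               lesion_counts = lesion_counts, noise_sd = noise_sd,
               illumination_gradient = stats::runif(1, 0, 0.2), seed = seed)
  })
}

# soft circular stamp coverage in [0,1] with a 1-px anti-alias ramp
circle_cov <- function(rr, cc, center, radius) {
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  pmin(1, pmax(0, radius + 0.5 - d))
}

blend_color <- function(planes, cov, color) {
  for (ch in 1:3) planes[[ch]] <- (1 - cov) * planes[[ch]] + cov * color[ch]
  planes
}

#' Render a synthetic fundus image with ground truth
#'
#' @param spec a [synth_spec()].
#' @param render_vessels if `FALSE`, vessel paths are still drawn internally
#'   (so the random stream is identical) but not rendered into the image --
#'   this yields the vessel-free twin used to assess inpainting.
#' @return list of class `synth_fundus` with elements `image` (H x W x 3,
#'   0--255) and `truth` (list: `disc_circle` with 0-based `center` and
#'   `radius`, binary `vessel_mask`, `lesion_coords` data frame with 0-based
#'   row/col, and `label`, a [label_vector()]).
#' @export
generate_fundus <- function(spec, render_vessels = TRUE) {
  stopifnot(inherits(spec, "synth_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ctr <- spec$disc_center; R <- spec$disc_radius
  if (dist_center_to_frame(ctr, H, W) > R)
    stop("invalid spec: disc lies entirely outside the frame")

  with_seed(spec$seed, {
    rr <- matrix(seq_len(H) - 1, H, W)
    cc <- matrix(rep(seq_len(W) - 1, each = H), H, W)
    d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
    cov <- pmin(1, pmax(0, R + 0.5 - d))

    shade <- pmax(0.55, 1 - 0.35 * (d / R)^2) *
      (1 + spec$illumination_gradient * (cc - ctr[2]) / R)
    shade <- pmin(pmax(shade, 0.4), 1.3)
    base <- c(185, 118, 52)
    planes <- lapply(base, function(v) v * shade)

    # optic disc (bright) and macula (dark), placed on opposite sides
    od_ctr <- c(ctr[1], ctr[2] + 0.45 * R)
    od_r <- 0.18 * R
    od_cov <- circle_cov(rr, cc, od_ctr, od_r)
    planes <- blend_color(planes, od_cov * 0.9, c(235, 208, 162))
    mac_ctr <- c(ctr[1], ctr[2] - 0.40 * R)
    mac_cov <- circle_cov(rr, cc, mac_ctr, 0.22 * R)
    for (ch in 1:3) planes[[ch]] <- planes[[ch]] * (1 - 0.22 * mac_cov)

    # vessels: jittered random walks from the optic disc, width 1-3 px
    vessel_mask <- matrix(0L, H, W)
    if (spec$n_vessels > 0) {
      for (v in seq_len(spec$n_vessels)) {
        pts <- vessel_walk(od_ctr, ctr, R, H, W)
        wd <- sample(1:3, 1L)
        stamp_path(vessel_mask, pts, wd) -> vessel_mask
        if (stats::runif(1) < 0.5 && nrow(pts) > 20) {   # one side branch
          k <- sample(10:(nrow(pts) - 5), 1L)
          bpts <- vessel_walk(pts[k, ], ctr, R, H, W)
          vessel_mask <- stamp_path(vessel_mask, bpts, max(1L, wd - 1L))
        }
      }
      vessel_mask[d > R - 1] <- 0L   # vessels only inside the disc
    }

    # lesions
    lesions <- render_lesions(planes, rr, cc, ctr, R, od_ctr, od_r, mac_ctr,
                              spec$lesion_counts)
    planes <- lesions$planes
    haze <- "haze" %in% lesions$coords$tag

    if (render_vessels && any(vessel_mask > 0)) {
      vfac <- c(0.45, 0.38, 0.50)
      vm <- vessel_mask > 0
      for (ch in 1:3) planes[[ch]][vm] <- planes[[ch]][vm] * vfac[ch]
    }

    if (haze) for (ch in 1:3)
      planes[[ch]] <- 0.62 * planes[[ch]] + 0.38 * 215

    # sensor noise on the disc; truncated dark noise on the background
    n <- H * W
    bg <- if (spec$noise_sd > 0)
      matrix(pmin(19, abs(stats::rnorm(n, 0, spec$noise_sd))), H, W)
    else matrix(0, H, W)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      pl <- planes[[ch]]
      if (spec$noise_sd > 0) pl <- pl + stats::rnorm(n, 0, spec$noise_sd)
      img[, , ch] <- round(clip8(cov * pl + (1 - cov) * bg))
    }

    present <- unique(lesion_tag_classes[lesions$coords$tag])
    label <- label_vector(if (length(present)) present else "N")

    structure(list(
      image = img,
      truth = list(
        disc_circle = list(center = ctr, radius = R),
        vessel_mask = vessel_mask,
        lesion_coords = lesions$coords,
        label = label
      )
    ), class = "synth_fundus")
  })
}

#' @export
print.synth_fundus <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("synthetic fundus %dx%d, disc r=%.0f at (%.0f, %.0f), label %s\n",
              dim(x$image)[1], dim(x$image)[2], tr$disc_circle$radius,
              tr$disc_circle$center[1], tr$disc_circle$center[2],
              as_bitstring(tr$label)))
  invisible(x)
}

vessel_walk <- function(start, disc_ctr, R, H, W, step = 1.5, max_steps = 400) {
  ang <- stats::runif(1, 0, 2 * pi)
  pos <- start
  pts <- matrix(NA_real_, max_steps, 2)
  for (i in seq_len(max_steps)) {
    pos <- pos + step * c(sin(ang), cos(ang))
    ang <- ang + stats::rnorm(1, 0, 0.18)
    if (sqrt(sum((pos - disc_ctr)^2)) > R - 2) break
    pts[i, ] <- pos
  }
  pts[stats::complete.cases(pts), , drop = FALSE]
}

# stamp a polyline of given width into a binary mask (0-based coordinates)
stamp_path <- function(mask, pts, width) {
  if (nrow(pts) == 0L) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  half <- (width - 1) / 2
  offs <- expand.grid(dr = -ceiling(half):ceiling(half),
                      dc = -ceiling(half):ceiling(half))
  offs <- offs[offs$dr^2 + offs$dc^2 <= (half + 0.5)^2, , drop = FALSE]
  r <- round(rep(pts[, 1], each = nrow(offs)) + offs$dr) + 1L
  c <- round(rep(pts[, 2], each = nrow(offs)) + offs$dc) + 1L
  ok <- r >= 1L & r <= H & c >= 1L & c <= W
  mask[cbind(r[ok], c[ok])] <- 1L
  mask
}

render_lesions <- function(planes, rr, cc, ctr, R, od_ctr, od_r, mac_ctr,
                           lesion_counts) {
  coords <- data.frame(row = numeric(0), col = numeric(0),
                       tag = character(0), stringsAsFactors = FALSE)
  add <- function(row, col, tag)
    coords <<- rbind(coords, data.frame(row = row, col = col, tag = tag,
                                        stringsAsFactors = FALSE))
  rand_pos <- function(rmax = 0.72) {
    repeat {
      a <- stats::runif(1, 0, 2 * pi); rad <- R * rmax * sqrt(stats::runif(1))
      p <- ctr + rad * c(sin(a), cos(a))
      if (p[1] >= 1 && p[1] <= nrow(rr) - 2 && p[2] >= 1 && p[2] <= ncol(rr) - 2)
        return(p)
    }
  }
  for (tag in names(lesion_counts)) {
    k <- lesion_counts[[tag]]
    if (k < 1) next
    for (i in seq_len(k)) {
      if (tag == "exudate") {
        p <- rand_pos(); s <- stats::runif(1, 1.5, 3.5)
        planes <- blend_color(planes, circle_cov(rr, cc, p, s), c(240, 228, 130))
        add(p[1], p[2], tag)
      } else if (tag == "hemorrhage") {
        p <- rand_pos(); s <- stats::runif(1, 2.5, 5)
        planes <- blend_color(planes, circle_cov(rr, cc, p, s), c(95, 22, 18))
        add(p[1], p[2], tag)
      } else if (tag == "microaneurysm") {
        p <- rand_pos(); s <- stats::runif(1, 0.9, 1.6)
        planes <- blend_color(planes, circle_cov(rr, cc, p, s), c(110, 28, 22))
        add(p[1], p[2], tag)
      } else if (tag == "drusen") {
        p <- mac_ctr + stats::rnorm(2, 0, 0.12 * R); s <- stats::runif(1, 1.5, 3)
        planes <- blend_color(planes, circle_cov(rr, cc, p, s), c(225, 205, 140))
        add(p[1], p[2], tag)
      } else if (tag == "flame") {
        p <- rand_pos(0.6); a <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 8, 16)
        t <- seq(0, len, by = 1)
        pts <- cbind(p[1] + t * sin(a), p[2] + t * cos(a))
        m <- matrix(0L, nrow(rr), ncol(rr))
        m <- stamp_path(m, pts, 2L)
        planes <- blend_color(planes, 0.9 * (m > 0), c(90, 20, 16))
        add(p[1], p[2], tag)
      } else if (tag == "cup") {
        planes <- blend_color(planes, circle_cov(rr, cc, od_ctr, 0.8 * od_r),
                              c(246, 228, 190))
        add(od_ctr[1], od_ctr[2], tag)
      } else if (tag == "crescent") {
        # pale crescent hugging the temporal edge of the optic disc
        dd <- sqrt((rr - od_ctr[1])^2 + (cc - od_ctr[2])^2)
        ring <- dd >= od_r & dd <= 1.6 * od_r & (cc - od_ctr[2]) > 0
        planes <- blend_color(planes, 0.85 * ring, c(228, 206, 170))
        add(od_ctr[1], od_ctr[2] + 1.3 * od_r, tag)
      } else if (tag == "patch") {
        p <- rand_pos(); s <- stats::runif(1, 5, 9)
        planes <- blend_color(planes, 0.8 * circle_cov(rr, cc, p, s),
                              c(120, 120, 120))
        add(p[1], p[2], tag)
      } else if (tag == "haze") {
        add(ctr[1], ctr[2], tag)   # global veil, applied after compositing
      }
    }
  }
  list(planes = planes, coords = coords)
}

#' Generate a synthetic two-eye patient dataset with manifest
#'
#' Writes `n` patients (a left and a right PNG each) plus `manifest.csv` with
#' columns `id, left_image, right_image, left_keywords, right_keywords,
#' final_label` (8-char bitstring, order N,D,G,C,A,H,M,O). Each patient's
#' condition is drawn from `class_mix`; the left eye always carries the
#' condition, the right eye carries it with probability 1/2 (otherwise it is
#' normal), mirroring datasets where the patient label is the verified union
#' of per-eye findings.
#'
#' @param n number of patients (>= 1).
#' @param class_mix named probability vector over the classes
#'   N, D, G, C, A, H, M, O (any subset); must sum to 1.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param out_dir output directory (created if needed).
#' @param image_size image size in pixels (square).
#' @param n_vessels,noise_sd,clip_fraction passed to the per-image specs.
#' @return the manifest as a data frame, invisibly; also written as
#'   `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(n, class_mix = c(N = 0.5, D = 0.5), seed = 1L,
                             out_dir = tempfile("synthfundus"),
                             image_size = 256, n_vessels = 6, noise_sd = 2,
                             clip_fraction = 0.1) {
  stopifnot(n >= 1)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (!all(names(class_mix) %in% names(synth_keywords)))
    stop("class_mix names must be among N,D,G,C,A,H,M,O")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create out_dir: ", out_dir)
  if (file.access(out_dir, 2) != 0) stop("out_dir is not writable: ", out_dir)

  conditions <- with_seed(seed, {
    cond <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    right_norm <- stats::runif(n) < 0.5
    list(cond = cond, right_norm = right_norm)
  })

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("p%05d", i)
    cond_l <- conditions$cond[i]
    cond_r <- if (conditions$right_norm[i]) "N" else conditions$cond[i]
    specs <- list()
    imgs <- list()
    for (eye in c("left", "right")) {
      cond <- if (eye == "left") cond_l else cond_r
      s <- (as.numeric(seed) * 7919 + i * 2 + (eye == "right")) %% 2147483647
      sp <- random_synth_spec(as.integer(s), image_size = image_size,
                              clip_fraction = clip_fraction,
                              n_vessels = n_vessels,
                              lesion_counts = condition_lesions[[cond]],
                              noise_sd = noise_sd)
      imgs[[eye]] <- generate_fundus(sp)
      write_fundus(imgs[[eye]]$image, file.path(out_dir, paste0(id, "_", eye, ".png")))
    }
    final <- union_and_verify(imgs$left$truth$label, imgs$right$truth$label)$label
    rows[[i]] <- data.frame(
      id = id,
      left_image = paste0(id, "_left.png"),
      right_image = paste0(id, "_right.png"),
      left_keywords = synth_keywords[[cond_l]],
      right_keywords = synth_keywords[[cond_r]],
      final_label = as_bitstring(final),
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
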