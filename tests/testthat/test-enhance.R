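test_that("channel extraction returns the untouched plane", {
  img <- array(0, c(8, 8, 3)); img[, , 2] <- 255
  expect_equal(extract_channel(img, "G"), matrix(255, 8, 8))
  expect_equal(extract_channel(img, "R"), matrix(0, 8, 8))
  expect_error(extract_channel(matrix(0, 8, 8), "G"), "RGB")

  f <- generate_fundus(synth_spec(seed = 5))
  expect_identical(extract_channel(f$image, "G"), f$image[, , 2])
})

test_that("CLAHE is flat on constants, monotone, and matches the hand oracle", {
  m <- matrix(137, 40, 40)
  out <- clahe(m)
  expect_lte(max(abs(out - 137)), 2)            # constant up to rounding
  expect_equal(length(unique(as.vector(out))), 1)

  # two-level image keeps its ordering (equalization is monotone per tile)
  two <- matrix(c(rep(50, 800), rep(200, 800)), 40, 40)
  o2 <- clahe(two)
  expect_gte(min(o2[two == 200]), max(o2[two == 50]))

  # single tile, no clipping, L = 16, intensities 0..15: direct evaluation
  # of the normalized-histogram CDF mapping
  p <- matrix(0:15, 4, 4)
  o3 <- clahe(p, clahe_config(clip_limit = Inf, tile_grid = c(1, 1),
                              levels = 16))
  cdf <- cumsum(tabulate(p + 1, nbins = 16) / 16)
  expect_equal(o3, matrix(floor(15 * cdf[p + 1]), 4, 4))

  # monotone as a whole-image transform under a single tile
  x <- matrix(withr::with_seed(4, sample(0:255, 1024, TRUE)), 32, 32)
  o4 <- clahe(x, clahe_config(tile_grid = c(1, 1)))
  expect_false(is.unsorted(o4[order(as.vector(x))]))

  expect_equal(dim(clahe(array(100, c(16, 16, 3)))), c(16, 16, 3))
})

test_that("Gaussian blend has the exact constant closed form and sharpens", {
  for (v in c(0, 31, 128, 255))
    expect_true(all(gaussian_blend(matrix(v, 25, 37)) == 128))
  # closed form holds for any offset gamma
  expect_true(all(gaussian_blend(matrix(77, 16, 16),
                                 gaussian_blend_config(gamma = 40)) == 40))

  # bright blob on black: centre amplified above surroundings, with a
  # clipped-to-zero ring (unsharp behaviour); oracle by direct convolution
  blob <- matrix(0, 33, 33); blob[16:18, 16:18] <- 255
  cfg <- gaussian_blend_config(sigma = 1)
  ob <- gaussian_blend(blob, cfg)
  blur <- gaussian_blur(blob, 1)
  oracle <- round(pmin(pmax(4 * blob - 4 * blur + 128, 0), 255))
  expect_equal(ob, oracle)
  expect_gt(ob[17, 17], max(ob[1:10, 1:10]))
  ring <- ob[14:20, 14:20]; ring[3:5, 3:5] <- NA
  expect_true(any(ring == 0, na.rm = TRUE))

  # vessel contrast strictly increases on synthetic fundus images
  f <- generate_fundus(synth_spec(seed = 6, n_vessels = 8))
  g <- extract_channel(f$image, "G")
  eg <- gaussian_blend(g)
  vm <- f$truth$vessel_mask > 0
  contrast <- function(m) abs(mean(m[vm]) - mean(m[!vm & m > 19]))
  expect_gt(contrast(eg), contrast(g))
})

test_that("multiscale retinex is zero on constants and linear in weights", {
  expect_true(all(msr(matrix(200, 30, 30)) == 0))
  expect_true(all(msr(matrix(200, 30, 30), rescale = FALSE) == 0))

  # single positive bump: raw retinex positive at the bump centre
  g <- matrix(0, 41, 41)
  g <- 200 * exp(-((row(g) - 21)^2 + (col(g) - 21)^2) / (2 * 3^2))
  raw <- msr(g, msr_config(scales = 8, weights = 1), rescale = FALSE)
  expect_gt(raw[21, 21], 0)

  # equal weights equal the average of single-scale passes (linearity)
  img <- generate_fundus(synth_spec(seed = 2))$image[, , 2]
  r3 <- msr(img, rescale = FALSE)
  r1 <- Reduce(`+`, lapply(c(5, 35, 150), function(s)
    msr(img, msr_config(scales = s, weights = 1), rescale = FALSE))) / 3
  expect_lt(max(abs(r3 - r1)), 1e-10)

  out <- msr(img)
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 255))
  expect_identical(out, msr(img))                 # deterministic
})

test_that("named variants compose crop and operators as defined", {
  f <- generate_fundus(synth_spec(seed = 9, noise_sd = 0))
  hp <- hough_params(nonzero_threshold = 19)

  vg <- apply_variant(f$image, "green", hp, out_size = 128)
  expect_true(is.matrix(vg))

  crop_only <- apply_variant(f$image, "cropped", hp, out_size = 128)
  expect_identical(crop_only, crop_roi(f$image, hp, out_size = 128)$image)

  gc <- apply_variant(f$image, "green_clahe", hp, out_size = 128)
  expect_identical(gc, clahe(extract_channel(
    crop_roi(f$image, hp, out_size = 128)$image, "G")))

  orig <- apply_variant(f$image, "original", hp, out_size = 64)
  expect_equal(dim(orig), c(64, 64, 3))

  expect_error(apply_variant(f$image, "sepia"), "unknown variant")
})
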