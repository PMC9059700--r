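test_that("detect_circles recovers a centred disc and rejects empty images", {
  f <- generate_fundus(synth_spec(seed = 1, disc_center = c(127.5, 127.5),
                                  disc_radius = 100))
  cand <- detect_circles(f$image)
  expect_gt(nrow(cand), 0)
  expect_lt(sqrt((cand$row[1] - 127.5)^2 + (cand$col[1] - 127.5)^2), 3)
  expect_lt(abs(cand$radius[1] - 100), 5)
  # candidates sorted by score, pairwise centres >= min distance apart
  expect_false(is.unsorted(rev(cand$score)))
  if (nrow(cand) > 1) {
    dmat <- as.matrix(stats::dist(cand[, c("row", "col")]))
    expect_true(all(dmat[upper.tri(dmat)] >= 20))
  }

  expect_equal(nrow(detect_circles(matrix(0, 64, 64))), 0)
  expect_error(detect_circles(matrix(0, 0, 0)), "non-empty")
})

test_that("two separated discs give two distinct candidates", {
  img <- plain_disc(256, 512, c(128, 130), 80)
  img2 <- plain_disc(256, 512, c(128, 330), 80)
  both <- pmax(img, img2)
  cand <- detect_circles(both)
  expect_gte(nrow(cand), 2)
  d12 <- sqrt((cand$row[1] - cand$row[2])^2 + (cand$col[1] - cand$col[2])^2)
  expect_gt(d12, 150)
})

test_that("circle selection enforces the non-zero-outside margin rule", {
  f <- generate_fundus(synth_spec(seed = 12, disc_center = c(127.5, 127.5),
                                  disc_radius = 90, noise_sd = 0))
  # a spurious high-scoring small circle inside the disc must lose to the
  # true disc, which is the first candidate covering all non-zero pixels
  spurious <- data.frame(row = 127.5, col = 127.5, radius = 30, score = 999)
  truecirc <- data.frame(row = 127.5, col = 127.5, radius = 90, score = 100)
  sel <- select_fundus_circle(f$image, rbind(spurious, truecirc), hp_synth)
  expect_equal(sel$radius, 90)

  sel2 <- select_fundus_circle(f$image, truecirc, hp_synth)
  expect_equal(sel2$radius, 90)

  expect_error(select_fundus_circle(f$image, NULL), "no circle candidates")
})

test_that("clipped discs select a frame-clamped box that passes the margin test", {
  f <- generate_fundus(synth_spec(seed = 3, disc_center = c(128, 20),
                                  disc_radius = 100))
  res <- crop_roi(f$image, hp_synth)
  b <- res$box
  expect_equal(b$method, "hough")
  expect_equal(unname(b$col_lo), 0)        # clamped at the clipped edge
  expect_true(b$row_lo >= 0 && b$row_hi <= 256 &&
              b$col_lo >= 0 && b$col_hi <= 256)
  nz <- which(pmax(f$image[, , 1], f$image[, , 2], f$image[, , 3]) > 19)
  r <- (nz - 1) %% 256; cc <- (nz - 1) %/% 256
  outside <- sum(r < b$row_lo - 5 | r >= b$row_hi + 5 |
                 cc < b$col_lo - 5 | cc >= b$col_hi + 5)
  expect_equal(outside, 0)
})

test_that("crop_roi boxes match ground truth and fall back gracefully", {
  f <- generate_fundus(synth_spec(seed = 11, disc_center = c(128, 128),
                                  disc_radius = 80))
  res <- crop_roi(f$image, hp_synth)
  expect_equal(dim(res$image), c(256, 256, 3))
  b <- res$box
  expect_lt(abs(b$row_lo - 48), 6); expect_lt(abs(b$row_hi - 208), 6)
  expect_lt(abs(b$col_lo - 48), 6); expect_lt(abs(b$col_hi - 208), 6)

  blk <- crop_roi(array(0, c(64, 64, 3)))
  expect_equal(blk$box$method, "fallback")
  expect_equal(unname(c(blk$box$row_lo, blk$box$row_hi,
                        blk$box$col_lo, blk$box$col_hi)), c(0, 64, 0, 64))
})

test_that("cropping is idempotent up to a 2 px border", {
  f <- generate_fundus(synth_spec(seed = 21, disc_center = c(127.5, 127.5),
                                  disc_radius = 95))
  once <- crop_roi(f$image, hp_synth)
  twice <- crop_roi(once$image, hp_synth)
  b <- twice$box
  expect_lte(b$row_lo, 2); expect_lte(b$col_lo, 2)
  expect_gte(b$row_hi, 254); expect_gte(b$col_hi, 254)
})

test_that("Otsu largest-contour crop matches the Hough crop on clean discs", {
  f <- generate_fundus(synth_spec(seed = 12, disc_center = c(127.5, 127.5),
                                  disc_radius = 90, noise_sd = 0))
  bo <- otsu_contour_crop(f$image)$box
  bh <- crop_roi(f$image, hp_synth)$box
  expect_equal(bo$method, "otsu")
  for (side in c("row_lo", "row_hi", "col_lo", "col_hi"))
    expect_lt(abs(bo[[side]] - bh[[side]]), 5)

  # all-zero image: whole-frame fallback
  z <- otsu_contour_crop(array(0, c(32, 32, 3)))
  expect_equal(z$box$method, "fallback")
  expect_equal(unname(c(z$box$row_lo, z$box$row_hi)), c(0, 32))

  # faint disc barely above a dim background: the baseline may clip the
  # disc, but it must still return a valid in-frame box
  faint <- plain_disc(128, 128, c(64, 64), 40, color = c(10, 10, 10)) + 15
  fb <- otsu_contour_crop(faint)$box
  expect_true(fb$row_lo >= 0 && fb$row_hi <= 128 && fb$row_lo < fb$row_hi)
})

test_that("detected boxes track the true disc box across varied geometry", {
  hits <- 0
  for (s in 1:15) {
    f <- generate_fundus(random_synth_spec(s + 100, clip_fraction = 0.2))
    b <- crop_roi(f$image, hp_synth)$box
    gt <- gt_disc_box(f$truth, 256, 256)
    hits <- hits + (box_iou(b, gt) >= 0.9)
  }
  expect_gte(hits, 14)
})
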