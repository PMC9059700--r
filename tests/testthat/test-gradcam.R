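test_that("zero gradients give identically zero maps", {
  act <- withr::with_seed(1, array(runif(64), c(4, 4, 4)))
  hm <- gradcam(act, array(0, dim(act)))
  expect_true(all(hm$raw == 0))
  expect_true(all(hm$normalized == 0))
  expect_false(any(hm$mask))
  expect_error(gradcam(act, array(0, c(4, 4, 2))), "identical shapes")
})

test_that("a single indicator activation thresholds back to its patch", {
  act <- array(0, c(4, 4, 1)); act[2:3, 2:3, 1] <- 1
  hm <- gradcam(act, array(1, c(4, 4, 1)))
  expect_equal(unname(which(hm$mask)), unname(which(act[, , 1] > 0)))

  # upscaled to image size: mask covers the patch interior away from the
  # interpolation band at the patch border
  hm32 <- gradcam(act, array(1, c(4, 4, 1)), size = c(32, 32))
  expect_true(all(hm32$mask[14:18, 14:18]))
  expect_false(any(hm32$mask[1:4, ]))
})

test_that("the raw map is the rectified gradient-weighted activation sum", {
  a1 <- matrix(1:16 / 4, 4, 4); a2 <- matrix(seq(4, -4, length.out = 16), 4, 4)
  act <- array(c(a1, a2), c(4, 4, 2))
  g1 <- matrix(0.5, 4, 4); g2 <- matrix(-0.25, 4, 4)
  hm <- gradcam(act, array(c(g1, g2), c(4, 4, 2)))
  hand <- pmax(0.5 * a1 + (-0.25) * a2, 0)     # weights are gradient means
  expect_equal(hm$raw, hand)
})

test_that("the mask is exactly the >= 100 set and scale invariant", {
  act <- withr::with_seed(5, array(runif(128), c(8, 8, 2)))
  grad <- withr::with_seed(6, array(rnorm(128), c(8, 8, 2)))
  hm <- gradcam(act, grad)
  expect_identical(hm$mask, hm$normalized >= 100)
  hm_scaled <- gradcam(act * 37.5, grad)       # positive rescale of raw map
  expect_equal(hm$normalized, hm_scaled$normalized)
  expect_identical(hm$mask, hm_scaled$mask)
})

test_that("contour overlays differ from the input only on contour pixels", {
  f <- generate_fundus(synth_spec(seed = 3))$image
  act <- array(0, c(8, 8, 1)); act[3:5, 3:5, 1] <- 1
  hm <- gradcam(act, array(1, c(8, 8, 1)), size = c(256, 256))
  res <- heatmap_to_contours(f, hm, score = 0.7)
  expect_length(res$contours, 1)
  diffpx <- which(apply(res$overlay != f, c(1, 2), any))
  bnd <- sort(unlist(lapply(res$contours, function(d) d$col * 256 + d$row + 1)))
  expect_equal(sort(diffpx), bnd)
  # green at score >= 0.5 (including the boundary case), red below
  px <- res$overlay[res$contours[[1]]$row[1] + 1,
                    res$contours[[1]]$col[1] + 1, ]
  expect_equal(px, c(0, 255, 0))
  res_half <- heatmap_to_contours(f, hm, score = 0.5)
  px2 <- res_half$overlay[res$contours[[1]]$row[1] + 1,
                          res$contours[[1]]$col[1] + 1, ]
  expect_equal(px2, c(0, 255, 0))
  res_red <- heatmap_to_contours(f, hm, score = 0.49)
  px3 <- res_red$overlay[res$contours[[1]]$row[1] + 1,
                         res$contours[[1]]$col[1] + 1, ]
  expect_equal(px3, c(255, 0, 0))

  # empty mask: overlay is the input and the contour list is empty
  zero <- gradcam(array(0, c(8, 8, 1)), array(0, c(8, 8, 1)),
                  size = c(256, 256))
  res0 <- heatmap_to_contours(f, zero, score = 0.9)
  expect_identical(res0$overlay, f)
  expect_length(res0$contours, 0)
})
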