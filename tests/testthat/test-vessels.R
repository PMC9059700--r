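test_that("segmentation backends are pluggable and validated", {
  f <- generate_fundus(synth_spec(seed = 4, n_vessels = 8))
  gt <- 255 * f$truth$vessel_mask

  ident <- segment_vessels(f$image, backend = function(img) gt)
  expect_identical(ident$raster, gt)

  expect_error(segment_vessels(f$image, backend = function(img) matrix(0, 2, 2)),
               "mismatched size")
  expect_error(segment_vessels(f$image, backend = "magic"), "backend")

  blk <- segment_vessels(array(0, c(64, 64, 3)))
  expect_true(all(clean_mask(blk)$raster == 0))
})

test_that("the naive backend recovers at least half of the true vessel pixels", {
  f <- generate_fundus(synth_spec(seed = 4, n_vessels = 8))
  m <- clean_mask(segment_vessels(f$image))
  gt <- f$truth$vessel_mask > 0
  recall <- sum(m$raster > 0 & gt) / sum(gt)
  expect_gte(recall, 0.5)
})

test_that("clean_mask applies the intensity and component-size rules exactly", {
  mk <- matrix(0, 20, 20); mk[1:10, 1:10] <- 200       # 100-px component
  expect_equal(sum(clean_mask(mk)$raster != 0), 100)   # boundary case kept
  mk[10, 10] <- 0                                       # now 99 px
  expect_true(all(clean_mask(mk)$raster == 0))
  expect_true(all(clean_mask(matrix(19, 20, 20))$raster == 0))
  # intensity 20 itself survives the "< 20" rule
  m20 <- matrix(0, 20, 20); m20[1:10, 1:10] <- 20
  expect_equal(sum(clean_mask(m20)$raster != 0), 100)
})

test_that("clean_mask is idempotent, shrinking, and matches a flood-fill oracle", {
  for (s in 1:6) {
    mk <- withr::with_seed(s, matrix(sample(c(0, 15, 25, 200), 32 * 32, TRUE,
                                            prob = c(.55, .15, .15, .15)),
                                     32, 32))
    for (conn in c(4L, 8L)) {
      cl <- clean_mask(vessel_mask(mk, conn), intensity_threshold = 20,
                       min_component_px = 12)
      # oracle: threshold, then flood-fill enumeration of components
      o <- mk; o[o < 20] <- 0
      lab <- flood_components(o, conn)
      if (max(lab) > 0) {
        sizes <- tabulate(lab[lab > 0])
        o[lab > 0 & sizes[pmax(lab, 1)] < 12] <- 0
      }
      expect_identical(cl$raster, o)
      # idempotence and monotonicity
      expect_identical(clean_mask(cl, 20, 12)$raster, cl$raster)
      expect_true(all(cl$raster[mk == 0] == 0))
      expect_true(all(mk[cl$raster != 0] != 0))
    }
  }
})

test_that("diffusion inpainting fills vessels toward the vessel-free image", {
  sp <- synth_spec(seed = 4, n_vessels = 8)
  f <- generate_fundus(sp)
  twin <- generate_fundus(sp, render_vessels = FALSE)
  expect_false(identical(f$image, twin$image))
  # the two renders differ only where vessels were painted
  vm <- f$truth$vessel_mask > 0
  expect_identical(f$image[rep(!vm, 3)], twin$image[rep(!vm, 3)])

  ip <- inpaint_vessels(f$image, vessel_mask(255 * f$truth$vessel_mask))
  err_in <- mean(abs(f$image - twin$image)[rep(vm, 3)])
  err_out <- mean(abs(ip - twin$image)[rep(vm, 3)])
  expect_lt(err_out, err_in)
  # untouched outside the mask
  expect_identical(ip[rep(!vm, 3)], f$image[rep(!vm, 3)])
})

test_that("inpainting degenerate cases behave as identities or errors", {
  f <- generate_fundus(synth_spec(seed = 2, n_vessels = 0))
  empty <- matrix(0, 256, 256)
  expect_identical(inpaint_vessels(f$image, empty), f$image)

  const <- matrix(90, 24, 24)
  some <- matrix(0, 24, 24); some[8:12, 8:16] <- 255
  expect_true(all(inpaint_vessels(const, some) == 90))

  expect_error(inpaint_vessels(const, matrix(1, 24, 24)), "entire image")
})
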