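test_that("generation is deterministic and respects the dark-background bound", {
  sp <- synth_spec(seed = 1, disc_center = c(127.5, 127.5), disc_radius = 100,
                   lesion_counts = list(exudate = 3, hemorrhage = 2))
  f1 <- generate_fundus(sp)
  f2 <- generate_fundus(sp)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$truth$vessel_mask, f2$truth$vessel_mask)

  # every pixel farther than radius + 1 from the centre is darker than 20
  d <- sqrt((row(f1$image[, , 1]) - 1 - 127.5)^2 +
            (col(f1$image[, , 1]) - 1 - 127.5)^2)
  outside <- d > 101
  for (ch in 1:3) expect_lt(max(f1$image[, , ch][outside]), 20)
})

test_that("empty content specs yield empty masks and invalid specs error", {
  f <- generate_fundus(synth_spec(seed = 2, n_vessels = 0))
  expect_true(all(f$truth$vessel_mask == 0))
  expect_equal(nrow(f$truth$lesion_coords), 0)
  expect_equal(as_bitstring(f$truth$label), "10000000")

  expect_error(synth_spec(disc_radius = 10),          # < image_size / 8
               "disc_radius")
  expect_error(synth_spec(clip_fraction = 0.5), "clip_fraction")
  expect_error(generate_fundus(synth_spec(seed = 1,
                                          disc_center = c(-500, -500))),
               "outside the frame")
})

test_that("vessel mask stays inside the disc and labels reflect lesions", {
  f <- generate_fundus(synth_spec(seed = 7, n_vessels = 8,
                                  lesion_counts = list(drusen = 5, cup = 1)))
  ctr <- f$truth$disc_circle$center; R <- f$truth$disc_circle$radius
  idx <- which(f$truth$vessel_mask > 0)
  d <- sqrt(((idx - 1) %% 256 - ctr[1])^2 + ((idx - 1) %/% 256 - ctr[2])^2)
  expect_true(all(d <= R))
  expect_equal(as_bitstring(f$truth$label), "00101000")   # G + A
  expect_gte(sum(as.integer(f$truth$label)), 1)
})

test_that("the rendered disc boundary recovers the specified circle", {
  for (s in c(3, 8, 15)) {
    sp <- random_synth_spec(s, image_size = 192)
    f <- generate_fundus(sp)
    bp <- disc_boundary_points(f$image)
    fit <- fit_circle(bp$rows, bp$cols)
    expect_lt(abs(fit["row"] - sp$disc_center[1]), 2)
    expect_lt(abs(fit["col"] - sp$disc_center[2]), 2)
    expect_lt(abs(fit["radius"] - sp$disc_radius), 2)
  }
})

test_that("generate_dataset writes a consistent, reproducible manifest", {
  dir1 <- withr::local_tempdir()
  man <- generate_dataset(10, class_mix = c(N = 1), seed = 3, out_dir = dir1,
                          image_size = 64)
  expect_equal(nrow(man), 10)
  expect_true(all(man$final_label == "10000000"))
  expect_true(all(file.exists(file.path(dir1, man$left_image))))
  expect_true(all(file.exists(file.path(dir1, man$right_image))))

  dir2 <- withr::local_tempdir()
  man2 <- generate_dataset(10, class_mix = c(N = 1), seed = 3, out_dir = dir2,
                           image_size = 64)
  expect_identical(man, man2)
  img1 <- read_fundus(file.path(dir1, man$left_image[1]))
  img2 <- read_fundus(file.path(dir2, man2$left_image[1]))
  expect_identical(img1, img2)

  expect_error(generate_dataset(5, class_mix = c(N = 0.7, D = 0.7)),
               "sum to 1")
})

test_that("class proportions follow the requested mix", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(200, class_mix = c(D = 0.5, N = 0.5), seed = 7,
                          out_dir = dir, image_size = 64)
  n_d <- sum(substr(man$final_label, 2, 2) == "1")
  # binomial(200, 0.5) 99% interval
  expect_gte(n_d, 70)
  expect_lte(n_d, 130)
})
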