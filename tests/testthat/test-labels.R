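test_that("keyword strings map to the documented label vectors", {
  expect_equal(as_bitstring(keywords_to_label("cataract")), "00010000")
  expect_equal(as_bitstring(keywords_to_label("normal fundus")), "10000000")
  expect_equal(as_bitstring(keywords_to_label("cataract, glaucoma")), "00110000")
  expect_equal(as_bitstring(keywords_to_label(
    "moderate non proliferative retinopathy")), "01000000")
  # hypertensive retinopathy must not leak into the DR class
  expect_equal(as_bitstring(keywords_to_label("hypertensive retinopathy")),
               "00000100")
  # unmatched phrases: catch-all O by default, error in strict mode
  expect_equal(as_bitstring(keywords_to_label("weird new finding")),
               "00000001")
  expect_error(keywords_to_label("weird new finding", strict = TRUE),
               "unknown keyword")
  expect_error(keywords_to_label(""), "non-empty")
})

test_that("two-eye union applies the normal-handling rule and verifies", {
  u <- union_and_verify(label_vector("00010000"), label_vector("10000000"),
                        declared = "00010000")
  expect_equal(as_bitstring(u$label), "00010000")   # Normal dropped
  expect_true(u$verified)

  both_norm <- union_and_verify(label_vector("10000000"),
                                label_vector("10000000"))
  expect_equal(as_bitstring(both_norm$label), "10000000")
  expect_true(is.na(both_norm$verified))

  mix <- union_and_verify(label_vector("01000000"), label_vector("00001000"))
  expect_equal(as_bitstring(mix$label), "01001000")  # bitwise OR

  mismatch <- union_and_verify(label_vector("01000000"),
                               label_vector("10000000"),
                               declared = "10000000")
  expect_false(mismatch$verified)
})

test_that("union is commutative and idempotent", {
  combos <- list(c("10000000", "00010000"), c("01100000", "00001001"),
                 c("10000000", "10000000"), c("00000001", "01000000"))
  for (p in combos) {
    a <- label_vector(p[1]); b <- label_vector(p[2])
    ab <- union_and_verify(a, b)$label
    ba <- union_and_verify(b, a)$label
    expect_identical(as.integer(ab), as.integer(ba))
    expect_identical(as.integer(union_and_verify(ab, ab)$label),
                     as.integer(ab))
  }
})

test_that("generated manifests verify in full against their keyword strings", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(25, class_mix = c(N = .4, D = .2, C = .2, G = .2),
                          seed = 5, out_dir = dir, image_size = 64)
  rel <- relabel_manifest(man)
  expect_true(all(rel$verified))
  expect_equal(rel$union_label, man$final_label)
})

test_that("patient aggregation is a label-wise maximum with one-eye fallback", {
  l <- c(0.9, 0.1, 0.3, 0, 0, 0, 0, 0)
  r <- c(0.2, 0.8, 0.1, 0, 0, 0, 0, 1)
  expect_equal(aggregate_patient(l, r), pmax(l, r))
  expect_equal(aggregate_patient(l, l), l)
  expect_equal(aggregate_patient(l, NULL), l)
  expect_equal(aggregate_patient(NULL, r), r)
  expect_error(aggregate_patient(l[1:5], r), "length 8")
  expect_error(aggregate_patient(NULL, NULL), "at least one eye")
})

test_that("DDR grades binarize with grade 5 excluded", {
  expect_equal(as.character(map_ddr_binary(0)), "normal")
  expect_equal(as.character(map_ddr_binary(3)), "abnormal")
  expect_equal(as.character(map_ddr_binary(5)), "excluded")
  expect_equal(as.character(map_ddr_binary(c(0, 1, 2, 3, 4, 5))),
               c("normal", rep("abnormal", 4), "excluded"))
  expect_error(map_ddr_binary(7), "0..5")

  # screening score is one minus the Normal-class score
  sc <- matrix(c(0.9, 0.2, rep(0.1, 14)), 2, 8)
  expect_equal(ddr_screening_score(sc), c(0.1, 0.8))
})
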