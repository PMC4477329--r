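test_that("unfold rescales 8-bit rasters and fold restores them bit-exactly", {
  r255 <- array(255, dim = c(2, 2, 3))
  img <- unfold(r255)
  expect_equal(img$data, matrix(1, 3, 4))

  px <- array(c(0, 128, 255), dim = c(1, 1, 3))
  expect_equal(unfold(px)$data, matrix(c(0, 128 / 255, 1), ncol = 1))

  set.seed(42)
  r <- array(runif(5 * 7 * 3), dim = c(5, 7, 3))
  expect_identical(fold(unfold(r)), r)
})

test_that("unfolding is row-major", {
  r <- array(0, dim = c(2, 3, 1))
  r[1, , 1] <- c(0.1, 0.2, 0.3)
  r[2, , 1] <- c(0.4, 0.5, 0.6)
  expect_equal(drop(unfold(r)$data), c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))

  lab <- fold_labels(c(1L, 2L, 3L, 4L, 5L, 6L), height = 2, width = 3)
  expect_equal(lab[1, ], 1:3)
  expect_equal(unfold_labels(lab), 1:6)
})

test_that("spectral image invariants are enforced", {
  expect_error(unfold(array(c(1, NA), dim = c(1, 2, 1))), "non-finite")
  expect_error(spectral_image(matrix(-0.1, 1, 1), 1, 1), "nonnegative")
  expect_error(spectral_image(matrix(1.5, 1, 1), 1, 1), "\\[0, 1\\]")
  expect_silent(spectral_image(matrix(1.5, 1, 1), 1, 1, kind = "lifted"))
  expect_error(spectral_image(matrix(0.5, 2, 6), 2, 2), "height \\* width")
})

test_that("16-bit and float rasters are handled", {
  r16 <- array(c(0, 65535, 32768, 100), dim = c(2, 2, 1))
  expect_equal(max(unfold(r16)$data), 1)
  rfl <- array(0.5, dim = c(2, 2, 2))
  expect_equal(unfold(rfl)$data, matrix(0.5, 2, 4))
  expect_error(unfold(array(1.7, dim = c(1, 1, 1))), "rescale manually")
})
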