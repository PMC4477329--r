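test_that("the shipped mixing matrix has the reference coherence to 4 decimals", {
  A <- synthetic_mixing_matrix()
  expect_equal(dim(A), c(3L, 5L))
  expect_equal(round(mutual_coherence(A), 4), 0.9995)
  expect_equal(round(average_coherence(A), 4), 0.9956)
})

test_that("noiseless phantoms close the estimation loop exactly", {
  ph <- make_phantom(height = 32, width = 32, snr_db = Inf)
  expect_equal(unname(estimate_profiles(ph$image, ph$sources)),
               unname(ph$mixing))
  expect_identical(ph$image$data, ph$clean$data)
})

test_that("noise seeds change the image but never the ground truth", {
  a <- make_phantom(height = 16, width = 16, snr_db = 70, seed = 1)
  b <- make_phantom(height = 16, width = 16, snr_db = 70, seed = 2)
  expect_false(identical(a$image$data, b$image$data))
  expect_identical(a$sources, b$sources)
  expect_identical(a$labels, b$labels)
})

test_that("layouts populate every component and validate their inputs", {
  for (lay in c("shapes", "bands")) {
    lab <- phantom_layout(40, 40, M = 5, layout = lay)
    expect_equal(sort(unique(as.vector(lab))), 1:5)
  }
  lab7 <- phantom_layout(20, 35, M = 7, layout = "bands")
  expect_equal(sort(unique(as.vector(lab7))), 1:7)
  expect_error(phantom_layout(10, 10, M = 4, layout = "shapes"), "M = 5")
  expect_error(phantom_layout(10, 10, M = 1), "at least 2")
})

test_that("non-default component counts require an explicit mixing matrix", {
  expect_error(make_phantom(height = 8, width = 8, M = 3), "supply a mixing")
  A <- easy_mixing(3, 3)
  ph <- make_phantom(height = 8, width = 9, M = 3, mixing = A)
  expect_equal(nrow(ph$sources), 3L)
  expect_equal(dim(ph$labels), c(8L, 9L))
})

test_that("mixing matrices outside [0, 1] are rejected for physical phantoms", {
  A <- synthetic_mixing_matrix() * 2
  expect_error(make_phantom(height = 8, width = 8, mixing = A), "\\[0, 1\\]")
})
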