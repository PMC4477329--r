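test_that("gaussian kernel has its closed-form values and symmetry", {
  x <- c(0.2, 0.5, 0.7)
  expect_equal(gaussian_kernel(x, x, 0.05), 1)
  z <- x + c(sqrt(2 * 0.05), 0, 0)   # squared distance = 2 sigma2
  expect_equal(gaussian_kernel(x, z, 0.05), exp(-1))
  set.seed(21)
  for (rep in 1:10) {
    a <- runif(3); b <- runif(3)
    expect_equal(gaussian_kernel(a, b, 0.02), gaussian_kernel(b, a, 0.02))
  }
  expect_error(gaussian_kernel(x, x, 0), "positive")
  expect_error(gaussian_kernel(x, x, -1), "positive")
})

test_that("anchor selection is deterministic and validates D", {
  ph <- make_phantom(height = 16, width = 16, snr_db = 40, seed = 1)
  k1 <- select_anchors(ph$image, D = 10, sigma2 = 0.01, seed = 7)
  k2 <- select_anchors(ph$image, D = 10, sigma2 = 0.01, seed = 7)
  expect_identical(k1$anchors, k2$anchors)
  expect_error(select_anchors(ph$image, D = 3, sigma2 = 0.01), "3 < D")
  expect_error(select_anchors(ph$image, D = 1000, sigma2 = 0.01), "3 < D")
})

test_that("cluster anchors reproduce images with exactly D distinct spectra", {
  ph <- make_phantom(height = 16, width = 16, snr_db = Inf)  # 5 distinct spectra
  km <- select_anchors(ph$image, D = 5, sigma2 = 0.01, seed = 1)
  got <- unname(km$anchors[order(km$anchors[, 1]), ])
  want <- unname(t(ph$mixing)[order(ph$mixing[1, ]), ])
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("subsample strategy with D = P returns every pixel spectrum", {
  ph <- make_phantom(height = 4, width = 4, snr_db = 40, seed = 2)
  km <- select_anchors(ph$image, D = 16, sigma2 = 0.01,
                       strategy = "subsample", seed = 3)
  expect_equal(km$anchors[order(km$anchors[, 1]), ],
               t(ph$image$data)[order(ph$image$data[1, ]), ])
})

test_that("the lift is invariant with respect to binary-orthogonal sources", {
  A <- synthetic_mixing_matrix()
  S <- random_sources(5, 80, seed = 5)
  X <- spectral_image(A %*% S, 8, 10)
  kmap <- select_anchors(X, D = 12, sigma2 = 0.01, seed = 1)
  lifted <- apply_ekm(X, kmap)
  B <- lift_basis(A, kmap)
  expect_equal(lifted$data, B %*% S)   # exact: every pixel is a column of A
  expect_true(all(lifted$data > 0) && all(lifted$data <= 1))
})

test_that("a very large kernel variance flattens the lift toward all-ones", {
  A <- synthetic_mixing_matrix()
  ph <- make_phantom(height = 16, width = 16, snr_db = Inf)
  kmap <- select_anchors(ph$image, D = 8, sigma2 = 1e6, seed = 1)
  B <- lift_basis(A, kmap)
  expect_true(all(B > 0.999))
  expect_gt(mutual_coherence(B), 1 - 1e-6)
})

test_that("lifted coherence decreases monotonically as sigma2 shrinks", {
  A <- synthetic_mixing_matrix()
  ph <- make_phantom(height = 32, width = 32, snr_db = 70, seed = 4)
  avg <- sapply(c(1, 0.1, 0.01, 0.001), function(s2) {
    kmap <- select_anchors(ph$image, D = 20, sigma2 = s2, seed = 9)
    average_coherence(lift_basis(A, kmap))
  })
  expect_true(all(diff(avg) < 0))
  expect_lt(avg[2], average_coherence(A))  # lift strictly decorrelates
})

test_that("dimension mismatches between image and anchors are rejected", {
  ph <- make_phantom(height = 8, width = 8, snr_db = Inf)
  kmap <- select_anchors(ph$image, D = 5, sigma2 = 0.01, seed = 1)
  bad <- spectral_image(matrix(0.5, 2, 4), 2, 2)
  expect_error(apply_ekm(bad, kmap), "channel count")
  expect_error(lift_basis(matrix(0.5, 2, 3), kmap), "anchor dimension")
})

test_that("the SNR-to-variance table is honored including its boundaries", {
  expect_equal(sigma2_for_snr(30), 0.001)
  expect_equal(sigma2_for_snr(29), 0.001)
  expect_equal(sigma2_for_snr(28), 0.01)
  expect_equal(sigma2_for_snr(20), 0.01)
  expect_equal(sigma2_for_snr(18), 0.01)
  expect_equal(sigma2_for_snr(17), 0.1)
  expect_equal(sigma2_for_snr(15), 0.1)
  expect_equal(sigma2_for_snr(14), 0.1)
  expect_equal(sigma2_for_snr(Inf), 0.001)
  expect_error(sigma2_for_snr(13.9), "outside the validated range")
})

test_that("coherence gain holds on generated highly coherent matrices", {
  # The lift decorrelates when the kernel variance sits at or below the
  # squared separations between profiles; the variance is therefore tied to
  # each matrix's own distance scale here.
  set.seed(31)
  for (rep in 1:100) {
    A <- random_coherent_matrix(3, 5, target_mu = 0.9992 + runif(1) * 5e-4,
                                seed = rep) * 0.9
    s2 <- stats::median(dist(t(A))^2) / 2
    ph <- make_phantom(height = 24, width = 24, M = 5, mixing = A,
                       snr_db = 70, seed = rep)
    kmap <- select_anchors(ph$image, D = 20, sigma2 = s2, seed = rep)
    expect_lt(average_coherence(lift_basis(A, kmap)), average_coherence(A))
  }
})
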