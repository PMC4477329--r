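test_that("the full kernel-lifted pipeline recovers a noiseless phantom exactly", {
  ph <- make_phantom(height = 48, width = 48, snr_db = Inf)
  for (method in c("ekm-nmu", "ekm-nmf_l0")) {
    res <- segment(ph$image, M = 5, method = method,
                   sigma2 = 0.1, dim = 20, seed = 1)
    expect_equal(segmentation_accuracy(res$sources, ph$sources), 1)
    # labels and sources are mutually consistent
    expect_equal(res$labels, fold_labels(res$sources, 48, 48))
    expect_false(is.null(res$coherence_lifted))
    expect_lte(res$coherence_lifted$mu_average,
               res$coherence_original$mu_average)
  }
})

test_that("unlifted runs carry no lifted diagnostics and echo provenance", {
  ph <- make_phantom(height = 24, width = 24, snr_db = Inf)
  res <- segment(ph$image, M = 5, method = "nmu", seed = 3)
  expect_null(res$coherence_lifted)
  expect_null(res$basis_lifted)
  expect_equal(res$provenance$method, "nmu")
  expect_equal(res$provenance$M, 5L)
  expect_null(res$provenance$sigma2)
  res2 <- segment(ph$image, M = 5, method = "ekm-nmu",
                  sigma2 = 0.05, dim = 10, seed = 3)
  expect_equal(res2$provenance$sigma2, 0.05)
  expect_equal(res2$provenance$dim, 10L)
})

test_that("segmentation is deterministic under a fixed seed", {
  ph <- make_phantom(height = 24, width = 24, snr_db = 40, seed = 6)
  r1 <- segment(ph$image, M = 5, method = "ekm-nmu",
                sigma2 = 0.1, dim = 15, seed = 2)
  r2 <- segment(ph$image, M = 5, method = "ekm-nmu",
                sigma2 = 0.1, dim = 15, seed = 2)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$basis_original, r2$basis_original)
})

test_that("k-means in Lab separates saturated colors and validates input", {
  cols <- rbind(c(0.95, 0.05, 0.05), c(0.05, 0.95, 0.05), c(0.05, 0.05, 0.95))
  S <- random_sources(3, 90, seed = 2)
  X <- spectral_image(t(cols) %*% S, 9, 10)
  pred <- kmeans_lab(X, M = 3, seed = 1)
  expect_equal(segmentation_accuracy(pred, S), 1)
  mono <- spectral_image(matrix(0.5, 1, 4), 2, 2)
  expect_error(kmeans_lab(mono, M = 2), "3-channel")
})

test_that("segment() refuses lifted input and unknown methods", {
  ph <- make_phantom(height = 8, width = 8, snr_db = Inf)
  kmap <- select_anchors(ph$image, D = 5, sigma2 = 0.1, seed = 1)
  expect_error(segment(apply_ekm(ph$image, kmap), M = 2), "physical")
  expect_error(segment(ph$image, M = 5, method = "pca"), "arg")
})

test_that("coherence_report reproduces the mixing coherence from true labels", {
  ph <- make_phantom(height = 32, width = 32, snr_db = Inf)
  rep_ <- coherence_report(ph$image, ph$sources)
  expect_equal(round(rep_$original$mu, 4), 0.9995)
  expect_equal(round(rep_$original$mu_average, 4), 0.9956)
  expect_null(rep_$lifted)
  kmap <- select_anchors(ph$image, D = 8, sigma2 = 1e6, seed = 1)
  rep2 <- coherence_report(ph$image, ph$sources, kmap)
  expect_gt(rep2$lifted$mu, 1 - 1e-6)      # kernel flattening limit
  expect_gt(rep2$lifted$mu_average, 1 - 1e-6)
})

test_that("block-mean downsampling shrinks the label map accordingly", {
  ph <- make_phantom(height = 32, width = 32, snr_db = Inf)
  res <- segment(ph$image, M = 5, method = "ekm-nmf_l0",
                 sigma2 = 0.1, dim = 10, seed = 1, downsample = 2)
  expect_equal(dim(res$labels), c(16L, 16L))
})

test_that("colorize maps labels through the palette and round-trips via PNG", {
  labels <- matrix(c(1L, 2L, 3L, 1L), 2, 2)
  img <- colorize(labels)
  expect_equal(img[1, 1, ], c(0, 0, 1))   # component 1 is blue
  expect_equal(img[2, 1, ], c(1, 0, 0))   # component 2 is red
  expect_equal(img[1, 2, ], c(0, 1, 0))   # component 3 is green
  # permuting the palette permutes colors only
  img2 <- colorize(labels, palette = default_palette(3)[c(2, 1, 3), ])
  expect_equal(img2[1, 1, ], c(1, 0, 0))
  expect_error(colorize(labels, palette = default_palette(2)), "at least M")

  tmp <- tempfile(fileext = ".png")
  write_label_map(labels, tmp)
  expect_identical(read_label_map(tmp), labels)
  unlink(tmp)
})

test_that("raster PNG input/output round-trips through read_raster", {
  ph <- make_phantom(height = 12, width = 10, snr_db = 50, seed = 1)
  tmp <- tempfile(fileext = ".png")
  write_raster(ph$image, tmp)
  back <- read_raster(tmp)
  expect_lt(max(abs(back$data - ph$image$data)), 1 / 254)  # 8-bit quantized
  expect_equal(c(back$height, back$width), c(12L, 10L))
  unlink(tmp)
})
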