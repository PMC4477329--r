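test_that("a high-SNR sweep succeeds everywhere and reports its threshold", {
  sw <- snr_sweep(snr_grid = c(55, 60), sigma2 = 0.1, D = 10,
                  height = 24, width = 24, replicates = 3, seed = 1)
  expect_named(sw, c("snr_db", "replicate", "accuracy", "sigma2", "D",
                     "method", "seed"))
  expect_true(all(sw$accuracy == 1))
  expect_equal(snr_threshold(sw), 55)
})

test_that("sweeps are reproducible and early stopping preserves the threshold", {
  a <- snr_sweep(snr_grid = c(50, 60), sigma2 = 0.1, D = 10,
                 height = 16, width = 16, replicates = 3, seed = 4)
  b <- snr_sweep(snr_grid = c(50, 60), sigma2 = 0.1, D = 10,
                 height = 16, width = 16, replicates = 3, seed = 4)
  expect_identical(a, b)
  e <- snr_sweep(snr_grid = c(50, 60), sigma2 = 0.1, D = 10,
                 height = 16, width = 16, replicates = 3, seed = 4,
                 early_stop = TRUE)
  expect_equal(snr_threshold(e), snr_threshold(a))
})

test_that("a failing sweep yields NA threshold and inputs are validated", {
  sw <- data.frame(snr_db = c(10, 10), replicate = 1:2, accuracy = c(0.4, 0.5))
  expect_true(is.na(snr_threshold(sw)))
  expect_error(snr_sweep(snr_grid = numeric(0), sigma2 = 0.1, D = 10),
               "non-empty")
  expect_error(snr_sweep(snr_grid = 20, sigma2 = 0.1, D = 10, replicates = 0),
               "at least 1")
})
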