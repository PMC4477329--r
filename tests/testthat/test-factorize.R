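test_that("nmf_l0 exactly recovers well-separated noiseless mixtures", {
  for (M in 2:6) {
    for (seed in 1:4) {
      A <- easy_mixing(6, M, seed = seed)
      S <- random_sources(M, 60, seed = seed + 100)
      X <- spectral_image(A %*% S, 6, 10)
      fit <- nmf_l0(X, M = M, seed = seed)
      expect_equal(segmentation_accuracy(fit$sources, S), 1)
    }
  }
})

test_that("nmf_l0 objective trace is monotone non-increasing", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(runif(8 * 120), 8, 120)
    fit <- nmf_l0(X, M = 4, iterations = 40, seed = seed)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
})

test_that("nmf_l0 validates M and max_nonzeros", {
  X <- matrix(runif(3 * 10), 3, 10)
  expect_error(nmf_l0(X, M = 1), "at least 2")
  expect_error(nmf_l0(X, M = 3, max_nonzeros = 0), "1..M")
  expect_error(nmf_l0(X, M = 3, max_nonzeros = 4), "1..M")
})

test_that("nmf_l0 is bitwise deterministic given a seed", {
  set.seed(1); X <- matrix(runif(5 * 80), 5, 80)
  f1 <- nmf_l0(X, M = 3, seed = 42)
  f2 <- nmf_l0(X, M = 3, seed = 42)
  expect_identical(f1$basis, f2$basis)
  expect_identical(f1$sources, f2$sources)
})

test_that("matching-pursuit coding with wider supports reduces the residual", {
  set.seed(9)
  A <- easy_mixing(6, 4, seed = 3)
  C <- matrix(stats::rexp(4 * 30), 4, 30) * (matrix(runif(4 * 30), 4, 30) < 0.5)
  X <- pmin(A %*% C, 1)
  f1 <- nmf_l0(X, M = 4, max_nonzeros = 1, iterations = 30, seed = 1)
  f2 <- nmf_l0(X, M = 4, max_nonzeros = 2, iterations = 30, seed = 1)
  expect_lte(min(f2$objective_trace), min(f1$objective_trace) + 1e-8)
})

test_that("nmu reconstructs a rank-one matrix with the first component", {
  x <- c(0.9, 0.5, 0.2); y <- runif(30, 0.1, 1)
  X <- x %o% y
  expect_warning(fit <- nmu(X, M = 2, polish = FALSE), "zero-filled")
  expect_lt(norm(X - fit$nmu_basis[, 1] %o% fit$nmu_coefficients[1, ], "F") /
              norm(X, "F"), 1e-6)
  expect_equal(sum(fit$nmu_coefficients[2, ]), 0)
})

test_that("nmu respects the underapproximation invariant", {
  set.seed(17)
  for (rep in 1:5) {
    X <- matrix(runif(6 * 60), 6, 60)
    fit <- nmu(X, M = 3, polish = FALSE)
    expect_lte(fit$max_violation, 1e-10)
    # cumulative reconstruction never exceeds X beyond clamping tolerance
    rec <- fit$nmu_basis %*% fit$nmu_coefficients
    expect_lte(max(rec - X), 1e-10)
    expect_true(all(fit$nmu_basis >= 0) && all(fit$nmu_coefficients >= 0))
  }
})

test_that("nmu results are bitwise deterministic", {
  set.seed(2); X <- matrix(runif(5 * 70), 5, 70)
  f1 <- nmu(X, M = 3)
  f2 <- nmu(X, M = 3)
  expect_identical(f1$basis, f2$basis)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$sources, f2$sources)
})

test_that("factorization sources are always binary and orthogonal", {
  set.seed(5); X <- matrix(runif(4 * 50), 4, 50)
  for (fit in list(nmf_l0(X, M = 3, seed = 1), nmu(X, M = 3))) {
    expect_silent(validate_sources(fit$sources))
  }
  expect_error(nmu(X, M = 1), "at least 2")
})
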