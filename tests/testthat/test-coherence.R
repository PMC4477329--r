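test_that("orthogonal, parallel and two-column cases give closed-form values", {
  expect_equal(mutual_coherence(diag(3)), 0)
  A2 <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(average_coherence(A2), mutual_coherence(A2))
  dup <- matrix(rep(c(1, 2, 0.5), 3), 3, 3)
  expect_equal(mutual_coherence(dup), 1)
  expect_equal(average_coherence(dup), 1)
})

test_that("coherences equal exhaustive pairwise brute force on random matrices", {
  set.seed(7)
  for (rep in 1:20) {
    A <- matrix(runif(4 * 6, 0.05, 1), 4, 6)
    co <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      co <- c(co, abs(sum(A[, i] * A[, j])) /
                (sqrt(sum(A[, i]^2)) * sqrt(sum(A[, j]^2))))
    }
    expect_equal(mutual_coherence(A), max(co))
    expect_equal(average_coherence(A), mean(co))
  }
})

test_that("coherence is invariant to positive column rescaling", {
  A <- synthetic_mixing_matrix()
  set.seed(11)
  for (rep in 1:5) {
    s <- runif(ncol(A), 0.1, 10)
    As <- sweep(A, 2L, s, "*")
    expect_equal(mutual_coherence(As), mutual_coherence(A), tolerance = 1e-12)
    expect_equal(average_coherence(As), average_coherence(A), tolerance = 1e-12)
  }
})

test_that("average coherence never exceeds mutual coherence", {
  set.seed(3)
  for (rep in 1:1000) {
    A <- matrix(runif(3 * 5, 0.01, 1), 3, 5)
    expect_lte(average_coherence(A), mutual_coherence(A) + 1e-14)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(mutual_coherence(matrix(1, 3, 1)), "M >= 2")
  Z <- cbind(c(1, 0, 0), c(0, 0, 0))
  expect_error(mutual_coherence(Z), "zero columns")
})
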