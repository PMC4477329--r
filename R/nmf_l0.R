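#' L0-sparseness-constrained nonnegative matrix factorization
#'
#' Factorizes a nonnegative channels-by-pixels matrix `X` as `A S` with
#' `A >= 0` (N x M) and at most `max_nonzeros` nonzero, nonnegative
#' coefficients per pixel column of `S`. The scheme alternates:
#'
#' * **sparse coding** — per pixel, choose the coefficient support of size
#'   `<= max_nonzeros` minimizing the squared residual. With the default
#'   `max_nonzeros = 1` (the binary/orthogonal segmentation regime) this is
#'   an exact argmin over the `M` single-atom nonnegative fits; for larger
#'   supports a nonnegative matching pursuit is used and is an approximation.
#' * **basis update** — per component, the exact nonnegative least-squares
#'   column given the fixed supports and coefficients (for `max_nonzeros = 1`
#'   the unconstrained least-squares solution is automatically nonnegative).
#'
#' With `max_nonzeros = 1` both half-steps are exact minimizers of the
#' reconstruction error, so the objective trace is non-increasing. The basis
#' is initialized from `M` k-means centres of a seeded pixel subsample;
#' near-parallel spectra make random initialization highly degenerate.
#'
#' @param image a [spectral_image()] (physical or lifted) or a nonnegative
#'   channels-by-pixels matrix.
#' @param M number of components, `M >= 2`.
#' @param max_nonzeros maximum nonzero coefficients per pixel, in `1..M`.
#' @param iterations iteration cap.
#' @param tol stop early when the relative objective change drops below this.
#' @param seed integer seed (initialization subsampling); identical inputs
#'   and seed give bitwise identical results.
#' @return A `factorization_result`: list with `basis` (N x M), `coefficients`
#'   (M x P, analog), `sources` (binary M x P, see [binarize_sources()]),
#'   `objective_trace` (squared Frobenius reconstruction error per iteration),
#'   `method`, `seed`.
#' @export
nmf_l0 <- function(image, M, max_nonzeros = 1L, iterations = 200L,
                   tol = 1e-6, seed = NULL) {
  X <- if (inherits(image, "spectral_image")) image$data else as.matrix(image)
  if (any(X < 0)) stop("X must be nonnegative")
  M <- as.integer(M)
  if (M < 2L) stop("the component count M must be at least 2")
  P <- ncol(X)
  if (M > P) warning("more components than pixels: factorization is degenerate")
  max_nonzeros <- as.integer(max_nonzeros)
  if (max_nonzeros < 1L || max_nonzeros > M) stop("max_nonzeros must lie in 1..M")

  A <- init_basis(X, M, seed)
  x2 <- sum(X^2)
  trace <- numeric(0)
  C <- NULL
  for (it in seq_len(iterations)) {
    cod <- if (max_nonzeros == 1L) code_single_atom(X, A) else
      code_pursuit(X, A, max_nonzeros)
    C <- cod$coefficients
    obj <- x2 - cod$explained
    trace <- c(trace, obj)
    A_new <- update_basis(X, C, A)
    A <- A_new
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (prev > 0 && abs(prev - obj) / prev < tol) break
    }
  }
  structure(
    list(basis = A, coefficients = C, sources = binarize_sources(C),
         objective_trace = trace, method = "nmf_l0", seed = seed),
    class = "factorization_result"
  )
}

#' @export
print.factorization_result <- function(x, ...) {
  cat(sprintf(
    "<factorization_result> method = %s, M = %d, P = %d, final objective = %.6g\n",
    x$method, nrow(x$coefficients), ncol(x$coefficients),
    utils::tail(x$objective_trace, 1)
  ))
  invisible(x)
}

# M seeded k-means centres of (a subsample of) the pixel spectra.
init_basis <- function(X, M, seed, max_sample = 20000L) {
  P <- ncol(X)
  with_seed(seed, {
    sub <- t(X[, if (P > max_sample) sample.int(P, max_sample) else seq_len(P),
               drop = FALSE])
    sub_u <- unique(sub)
    A <- if (nrow(sub_u) <= M) {
      t(sub_u[rep_len(seq_len(nrow(sub_u)), M), , drop = FALSE])
    } else {
      km <- NULL
      for (attempt in 1:10) {
        km <- tryCatch(
          suppressWarnings(stats::kmeans(sub, centers = M, iter.max = 50L)),
          error = function(e) NULL
        )
        if (!is.null(km)) break
      }
      if (is.null(km)) stop("k-means basis initialization failed repeatedly")
      t(unname(km$centers))
    }
    bad <- colSums(A^2) == 0
    A[, bad] <- rowMeans(X) + 1e-12
    A
  })
}

# Exact single-atom nonnegative sparse coding: per pixel the best
# one-component fit, enumerated over all M atoms.
code_single_atom <- function(X, A) {
  a2 <- colSums(A^2)
  AtX <- crossprod(A, X)                      # M x P
  Cfit <- pmax(AtX / a2, 0)
  gain <- Cfit * (2 * AtX - Cfit * a2)        # squared-error reduction per atom
  pick <- max.col(t(gain), ties.method = "first")
  sel <- cbind(pick, seq_len(ncol(X)))
  C <- matrix(0, nrow = ncol(A), ncol = ncol(X))
  C[sel] <- Cfit[sel]
  list(coefficients = C, explained = sum(gain[sel]))
}

# Greedy nonnegative matching pursuit with least-squares refit on the chosen
# support (negative refit coefficients are clamped and dropped). Approximate;
# used only for max_nonzeros > 1.
code_pursuit <- function(X, A, k) {
  M <- ncol(A)
  P <- ncol(X)
  C <- matrix(0, nrow = M, ncol = P)
  a2 <- colSums(A^2)
  explained <- 0
  for (p in seq_len(P)) {
    x <- X[, p]
    supp <- integer(0)
    for (step in seq_len(k)) {
      r <- x - A %*% C[, p, drop = FALSE]
      g <- pmax(drop(crossprod(A, r)), 0) / sqrt(a2)
      g[supp] <- -Inf
      m <- which.max(g)
      if (g[m] <= 0) break
      supp <- c(supp, m)
      cs <- stats::coef(stats::lm.fit(A[, supp, drop = FALSE], x))
      cs[is.na(cs) | cs < 0] <- 0
      C[, p] <- 0
      C[supp, p] <- cs
    }
    explained <- explained + sum(x^2) - sum((x - A %*% C[, p, drop = FALSE])^2)
  }
  list(coefficients = C, explained = explained)
}

# Alternating exact minimization under the binary/orthogonal source model:
# single-atom assignment + per-component least-squares basis, with empty
# components re-seeded to the worst-reconstructed pixel (re-seeding leaves
# the current objective unchanged, so the trace stays non-increasing).
# Used to polish an analog factorization into the constrained model.
refine_assignment <- function(X, A0, iterations = 50L, tol = 1e-10,
                              mode = c("unit", "analog")) {
  mode <- match.arg(mode)
  if (mode == "unit") {
    polish_engine(X, A0, as.integer(iterations), tol)
  } else {
    polish_engine_analog(X, A0, as.integer(iterations), tol)
  }
}

# Deterministic farthest-point basis: start at the largest-norm pixel
# spectrum, then repeatedly add the pixel farthest (Euclidean) from the
# current set. A standard seeding for alternating assignment schemes that is
# independent of the factorization path.
farthest_point_basis <- function(X, M) {
  P <- ncol(X)
  idx <- integer(M)
  idx[1] <- which.max(colSums(X^2))
  d2 <- colSums((X - X[, idx[1]])^2)
  for (m in seq_len(M - 1L)) {
    idx[m + 1L] <- which.max(d2)
    d2 <- pmin(d2, colSums((X - X[, idx[m + 1L]])^2))
  }
  X[, idx, drop = FALSE]
}

# Exact per-component least-squares basis columns given fixed coefficients.
# Components with all-zero coefficient rows keep their previous column so the
# objective cannot increase; they are surfaced via the "frozen" attribute.
update_basis <- function(X, C, A_old) {
  M <- nrow(C)
  A <- A_old
  single <- all(colSums(C != 0) <= 1L)
  if (single) {
    for (m in seq_len(M)) {
      w <- C[m, ]
      s2 <- sum(w^2)
      if (s2 > 0) A[, m] <- (X %*% w) / s2
    }
  } else {
    G <- tcrossprod(C)                       # M x M
    ok <- diag(G) > 0
    if (any(ok)) {
      sol <- tryCatch(
        t(solve(G[ok, ok, drop = FALSE], C[ok, , drop = FALSE] %*% t(X))),
        error = function(e) NULL
      )
      if (!is.null(sol)) A[, ok] <- pmax(sol, 0)
    }
  }
  frozen <- colSums(C != 0) == 0L
  attr(A, "frozen") <- sum(frozen)
  A
}
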