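#' Mutual coherence of a mixing matrix
#'
#' The mutual coherence of a matrix with columns \eqn{a_1, \dots, a_M} is the
#' worst-case normalized correlation between two distinct columns,
#' \deqn{\mu(A) = \max_{i \ne j} \frac{|\langle a_i, a_j\rangle|}{\|a_i\|_2 \|a_j\|_2},}
#' i.e. the largest absolute cosine between column pairs. For a mixing matrix
#' whose columns are component spectral profiles, values very close to 1 mean
#' near-parallel profiles and a mixture that is close to unidentifiable for
#' blind decomposition.
#'
#' @param A numeric matrix with `M >= 2` columns, none of them zero.
#' @return scalar in `[0, 1]` for nonnegative `A` (in general `<= 1`).
#' @seealso [average_coherence()]
#' @examples
#' mutual_coherence(diag(3))            # orthogonal columns -> 0
#' mutual_coherence(synthetic_mixing_matrix())
#' @export
mutual_coherence <- function(A) {
  max(pairwise_coherences(A))
}

#' Average coherence of a mixing matrix
#'
#' The arithmetic mean of the absolute normalized inner products over all
#' `M (M - 1) / 2` unordered column pairs — the average correlation between
#' component spectral profiles, reported alongside the worst case
#' [mutual_coherence()].
#'
#' @inheritParams mutual_coherence
#' @return scalar in `[0, 1]` for nonnegative `A`; always `<=`
#'   `mutual_coherence(A)`, with equality at `M = 2`.
#' @export
average_coherence <- function(A) {
  mean(pairwise_coherences(A))
}

#' Coherence report for a mixing matrix
#'
#' @inheritParams mutual_coherence
#' @return A `coherence_report`: list with elements `mu` (worst case) and
#'   `mu_average` (mean over unordered pairs).
#' @export
coherence_stats <- function(A) {
  co <- pairwise_coherences(A)
  structure(list(mu = max(co), mu_average = mean(co)),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf("mu = %.4f, mu_average = %.4f\n", x$mu, x$mu_average))
  invisible(x)
}

# |cos| between all unordered column pairs, as a vector of length M(M-1)/2.
pairwise_coherences <- function(A) {
  A <- as.matrix(A)
  if (ncol(A) < 2L) stop("coherence requires at least 2 columns (M >= 2)")
  nrm <- sqrt(colSums(A^2))
  if (any(nrm == 0)) stop("coherence is undefined for zero columns")
  G <- crossprod(sweep(A, 2L, nrm, "/"))
  co <- abs(G[upper.tri(G)])
  pmin(co, 1)  # guard rounding just above 1 for near-parallel columns
}
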