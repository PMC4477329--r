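#' Validate a binary orthogonal source matrix
#'
#' A source matrix `S` is `M x P` with entries in `{0, 1}` and exactly one 1
#' per column: each pixel carries exactly one component. Column-sum-one
#' binary columns imply that distinct rows have zero inner product (row
#' orthogonality), the constraint that makes blind decomposition of the
#' mixture `X = A S` unique up to scaling and permutation.
#'
#' @param S numeric matrix to validate.
#' @return `S`, invisibly, after validation; errors otherwise.
#' @export
validate_sources <- function(S) {
  S <- as.matrix(S)
  if (!all(S == 0 | S == 1)) stop("source matrix entries must be binary {0, 1}")
  if (!all(colSums(S) == 1)) {
    stop("each source matrix column must have exactly one active component")
  }
  invisible(S)
}

#' Convert between source matrices and label vectors
#'
#' `sources_to_labels` returns, per pixel, the index of the active component;
#' `labels_to_sources` builds the binary one-per-column matrix from labels.
#'
#' @param S binary `M x P` source matrix.
#' @return integer vector of length `P` with values in `1..M`.
#' @export
sources_to_labels <- function(S) {
  validate_sources(S)
  max.col(t(S), ties.method = "first")
}

#' @rdname sources_to_labels
#' @param labels integer vector with values in `1..M`.
#' @param M number of components; defaults to `max(labels)`.
#' @return binary `M x P` source matrix.
#' @export
labels_to_sources <- function(labels, M = max(labels)) {
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > M)) stop("labels must lie in 1..M")
  S <- matrix(0, nrow = M, ncol = length(labels))
  S[cbind(labels, seq_along(labels))] <- 1
  S
}

#' Binarize coefficient columns to one active component per pixel
#'
#' Converts an analog nonnegative coefficient matrix (components by pixels)
#' into a binary orthogonal source matrix: per pixel the component with the
#' maximal coefficient is set to 1, all others to 0. Ties are broken toward
#' the lowest component index. Pixels whose coefficient column is entirely
#' zero carry no evidence; they are assigned to component 1 and counted in
#' the `zero_columns` attribute so degenerate factorizations are visible.
#'
#' @param coefficients nonnegative numeric `M x P` matrix; columns must not
#'   be entirely `NaN`.
#' @return binary `M x P` source matrix with attribute `zero_columns`
#'   (number of all-zero input columns).
#' @examples
#' binarize_sources(matrix(c(0.2, 0.9, 0.1), ncol = 1))
#' @export
binarize_sources <- function(coefficients) {
  C <- as.matrix(coefficients)
  if (any(apply(is.na(C), 2L, all))) stop("coefficient columns must not be all-NaN")
  C[is.na(C)] <- -Inf
  zero <- colSums(C != 0) == 0L
  idx <- max.col(t(C), ties.method = "first")
  idx[zero] <- 1L
  S <- labels_to_sources(idx, M = nrow(C))
  attr(S, "zero_columns") <- sum(zero)
  S
}
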