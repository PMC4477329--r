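#' Nonnegative matrix underapproximation
#'
#' Factorizes a nonnegative channels-by-pixels matrix `X` into `M` rank-one
#' nonnegative terms under the elementwise underapproximation constraint
#' `U V <= X`. The constraint is what induces sparse, parts-based
#' coefficients without an explicit sparsity penalty: no term can "spend"
#' mass that belongs to another component.
#'
#' The fit has two phases. First, a recursive phase extracts the components
#' one by one: a rank-one pair `(x_j, y_j)` is fitted to the current
#' residual `R` by the standard Lagrangian alternating scheme (nonnegative
#' updates of unit-norm `x` and of `y`, multiplier matrix updated at a
#' `1/k` decaying rate), the coefficients are clipped per pixel so
#' `x_j y_j' <= R` holds exactly, the term is subtracted and the residual
#' clamped at zero. Second, a global phase refines all `M` factors jointly
#' on the original matrix under `U V <= X`, using Lagrangian multiplier
#' steps with one HALS pass over basis columns and coefficient rows per
#' step; this joint refinement is what disentangles components whose
#' profiles remain strongly correlated, which the greedy recursion alone
#' tends to merge. The procedure is deterministic (power-iteration
#' initialization); `seed` is accepted for interface parity and provenance.
#'
#' Because exact nonnegative factorizations of highly coherent mixtures are
#' not unique, the analog underapproximation factors can converge to a
#' rotated solution in which two components share a dominant factor. The
#' mixture model, however, constrains the sources to be binary with exactly
#' one active component per pixel, with unit coefficients; with
#' `polish = TRUE` (default) the engine therefore finishes with an
#' assignment polish: alternating exact minimization under that source
#' constraint (nearest-profile assignment / component-mean basis update,
#' empty components re-seeded to the worst-reconstructed pixel), started
#' from the underapproximation factors and, as a safeguard against their
#' local optima, from a deterministic farthest-point pixel basis — the
#' start reaching the lower reconstruction error wins. The polished basis
#' and one-hot coefficients are returned as `basis`/`coefficients` (so
#' `sources == binarize_sources(coefficients)`), and the recursive-phase
#' factors, which satisfy the underapproximation constraint exactly, are
#' kept in `nmu_basis` / `nmu_coefficients`.
#'
#' If the residual reaches zero before `M` components were extracted, the
#' remaining components are zero-filled with a warning.
#'
#' @param image a [spectral_image()] (physical or lifted) or a nonnegative
#'   channels-by-pixels matrix.
#' @param M number of components, `M >= 2`.
#' @param inner_iterations Lagrangian iterations per rank-one subproblem.
#' @param refine_iterations joint Lagrangian refinement steps (0 disables
#'   the global phase).
#' @param tol convergence tolerance (relative coefficient change in the
#'   recursive phase; relative error change in the global phase).
#' @param polish if `TRUE`, refine the final sources under the
#'   binary/orthogonal constraint of the mixture model (see Details).
#' @param seed recorded in the result; the engine itself is deterministic.
#' @return A `factorization_result` (see [nmf_l0()]) with `method = "nmu"`,
#'   `objective_trace` holding the residual Frobenius norm after each
#'   recursively extracted component, and `max_violation` the largest
#'   elementwise constraint violation observed before the exact per-pixel
#'   clip of the recursive phase.
#' @export
nmu <- function(image, M, inner_iterations = 100L, refine_iterations = 100L,
                tol = 1e-8, polish = TRUE, seed = NULL) {
  X <- if (inherits(image, "spectral_image")) image$data else as.matrix(image)
  if (any(X < 0)) stop("X must be nonnegative")
  M <- as.integer(M)
  if (M < 2L) stop("the component count M must be at least 2")
  fit <- nmu_engine(X, M, as.integer(inner_iterations),
                    as.integer(refine_iterations), tol)
  if (fit$components_fit < M) {
    warning(sprintf(
      "residual exhausted after %d of %d components; remainder zero-filled",
      fit$components_fit, M
    ))
  }
  basis <- fit$basis
  coefficients <- fit$coefficients
  if (polish && fit$components_fit > 0) {
    ref <- refine_assignment(X, basis)
    alt <- refine_assignment(X, farthest_point_basis(X, M))
    if (alt$objective < ref$objective) ref <- alt
    basis <- ref$basis
    coefficients <- ref$coefficients
  }
  structure(
    list(basis = basis, coefficients = coefficients,
         sources = binarize_sources(coefficients),
         nmu_basis = fit$recursive_basis,
         nmu_coefficients = fit$recursive_coefficients,
         objective_trace = fit$residual_trace[seq_len(max(fit$components_fit, 1L))],
         max_violation = fit$max_violation,
         components_fit = fit$components_fit,
         method = "nmu", seed = seed),
    class = "factorization_result"
  )
}
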