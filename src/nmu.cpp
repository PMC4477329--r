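// Nonnegative matrix underapproximation (NMU).
//
// Phase 1 (recursive): for each component a rank-one nonnegative pair
// (x, y) is fitted to the current residual R under the elementwise
// constraint x y' <= R via the Lagrangian alternating scheme with a 1/k
// decaying multiplier update rate; the coefficients are clipped per pixel
// so the constraint holds exactly before the term is subtracted and the
// residual clamped at zero.
//
// Phase 2 (global): all M factors are refined jointly on the original
// matrix, min ||X - U V||^2 subject to U, V >= 0 and U V <= X, again by
// Lagrangian multipliers (updated at a 1/k rate) with one HALS pass over
// the columns of U and rows of V per multiplier step. The joint phase is
// what disentangles components whose profiles remain highly correlated
// after the lift; the recursive phase provides a deterministic,
// parts-based starting point.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Leading nonnegative rank-one pair of a nonnegative matrix by power
// iteration (Perron vector), deterministic from a uniform start.
static void power_init(const mat& R, vec& x, vec& y, int iters = 20) {
  y.set_size(R.n_cols);
  y.fill(1.0 / std::sqrt((double)R.n_cols));
  x.set_size(R.n_rows);
  for (int i = 0; i < iters; ++i) {
    x = R * y;
    double nx = norm(x, 2);
    if (nx == 0) { x.zeros(); y.zeros(); return; }
    x /= nx;
    y = R.t() * x;
    double ny = norm(y, 2);
    if (ny == 0) { x.zeros(); y.zeros(); return; }
    y /= ny;
  }
  y = R.t() * x;            // unnormalized coefficients, x unit norm
  y.transform([](double v) { return v > 0 ? v : 0.0; });
}

// [[Rcpp::export]]
Rcpp::List nmu_engine(const arma::mat& X, int M, int inner_iterations,
                      int refine_iterations, double tol) {
  mat R = X;
  const uword D = R.n_rows, P = R.n_cols;
  mat U(D, (uword)M, fill::zeros);
  mat V((uword)M, P, fill::zeros);
  vec res_trace((uword)M, fill::zeros);
  double max_violation = 0.0;   // worst (x y' - R) entry before the exact clip
  int components_fit = 0;

  // ---- Phase 1: recursive rank-one underapproximation -------------------
  const double x_norm0 = std::sqrt(accu(X % X));
  for (int j = 0; j < M; ++j) {
    // residual numerically exhausted: remaining components stay zero
    if (std::sqrt(accu(R % R)) <= 1e-10 * x_norm0) break;
    vec x, y;
    power_init(R, x, y);
    if (norm(x, 2) == 0 || norm(y, 2) == 0) break;
    mat Lam(D, P, fill::zeros);
    vec y_prev = y;
    for (int k = 1; k <= inner_iterations; ++k) {
      x = R * y - Lam * y;                       // x <- [(R - Lam) y]+, unit
      x.transform([](double v) { return v > 0 ? v : 0.0; });
      double nx = norm(x, 2);
      if (nx == 0) break;
      x /= nx;
      y = R.t() * x - Lam.t() * x;               // y <- [(R - Lam)' x]+
      y.transform([](double v) { return v > 0 ? v : 0.0; });
      double rate = 1.0 / (k + 1);
      Lam = Lam - rate * (R - x * y.t());        // Lam <- [Lam - rate (R - xy')]+
      Lam.transform([](double v) { return v > 0 ? v : 0.0; });
      double dy = norm(y - y_prev, 2);
      double ny = norm(y, 2);
      y_prev = y;
      if (ny > 0 && dy / ny < tol) break;
    }
    if (norm(y, 2) == 0) break;
    // Exact underapproximation: clip y per pixel so x y' <= R elementwise.
    uvec act = find(x > 1e-12);
    if (act.n_elem > 0) {
      mat Rsub = R.rows(act);
      vec xsub = x.elem(act);
      for (uword p = 0; p < P; ++p) {
        if (y(p) <= 0) continue;
        double cap = (Rsub.col(p) / xsub).min();
        if (cap < y(p)) y(p) = cap > 0 ? cap : 0.0;
      }
    }
    mat approx = x * y.t();
    double viol = (approx - R).max();
    if (viol > max_violation) max_violation = viol;
    R -= approx;
    R.transform([](double v) { return v > 0 ? v : 0.0; });
    U.col(j) = x;
    V.row(j) = y.t();
    res_trace(j) = std::sqrt(accu(R % R));
    components_fit = j + 1;
  }

  // phase-1 factors satisfy the underapproximation exactly; keep a copy
  mat U_rec = U, V_rec = V;

  // ---- Phase 2: global joint refinement under U V <= X ------------------
  if (components_fit > 0 && refine_iterations > 0) {
    mat Lam(D, P, fill::zeros);
    double prev_err = datum::inf;
    for (int k = 1; k <= refine_iterations; ++k) {
      mat A = X - Lam;
      // HALS pass on U given V
      mat VVt = V * V.t();
      mat AVt = A * V.t();
      for (int j = 0; j < M; ++j) {
        double d = VVt(j, j);
        if (d <= 0) continue;
        vec u = (AVt.col(j) - U * VVt.col(j) + U.col(j) * d) / d;
        u.transform([](double v) { return v > 0 ? v : 0.0; });
        U.col(j) = u;
      }
      // HALS pass on V given U
      mat UtU = U.t() * U;
      mat UtA = U.t() * A;
      for (int j = 0; j < M; ++j) {
        double d = UtU(j, j);
        if (d <= 0) continue;
        rowvec v = (UtA.row(j) - UtU.row(j) * V + d * V.row(j)) / d;
        v.transform([](double w) { return w > 0 ? w : 0.0; });
        V.row(j) = v;
      }
      mat E = X - U * V;
      Lam = Lam - (1.0 / (k + 1)) * E;
      Lam.transform([](double v) { return v > 0 ? v : 0.0; });
      if (k % 10 == 0) {
        double err = std::sqrt(accu(E % E));
        if (prev_err < datum::inf &&
            std::abs(prev_err - err) <= tol * std::max(prev_err, 1e-300)) {
          break;
        }
        prev_err = err;
      }
    }
    // unit-norm basis columns so coefficient rows are scale-comparable
    for (int j = 0; j < M; ++j) {
      double n = norm(U.col(j), 2);
      if (n > 0) { U.col(j) /= n; V.row(j) *= n; }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("basis") = U,
    Rcpp::Named("coefficients") = V,
    Rcpp::Named("recursive_basis") = U_rec,
    Rcpp::Named("recursive_coefficients") = V_rec,
    Rcpp::Named("residual_trace") = res_trace,
    Rcpp::Named("max_violation") = max_violation,
    Rcpp::Named("components_fit") = components_fit);
}

// Alternating exact minimization under the binary (unit-coefficient)
// one-component-per-pixel source model: each pixel is assigned to its
// nearest basis column (the model says x_p = a_{m(p)} exactly), and each
// basis column is updated to the mean of its pixels; empty components are
// re-seeded at the worst-reconstructed pixel (a step that leaves the
// current objective unchanged, so the scheme is monotone).
// [[Rcpp::export]]
Rcpp::List polish_engine(const arma::mat& X, const arma::mat& A0,
                         int iterations, double tol) {
  const uword N = X.n_rows, P = X.n_cols, M = A0.n_cols;
  mat A = A0;
  uvec assign(P, fill::zeros);
  double prev = datum::inf, obj = datum::inf;
  const double x2 = accu(X % X);
  for (int it = 0; it < iterations; ++it) {
    vec a2 = sum(square(A), 0).t();
    mat AtX = A.t() * X;                     // M x P
    double explained = 0.0;
    for (uword p = 0; p < P; ++p) {
      double best = -datum::inf; uword bm = 0;
      for (uword m = 0; m < M; ++m) {
        double gain = 2.0 * AtX(m, p) - a2(m);   // -||x - a_m||^2 + ||x||^2
        if (gain > best) { best = gain; bm = m; }
      }
      assign(p) = bm; explained += best;
    }
    obj = x2 - explained;
    // empty components -> re-seed at the worst-reconstructed pixel
    uvec counts(M, fill::zeros);
    for (uword p = 0; p < P; ++p) counts(assign(p))++;
    uvec empty = find(counts == 0);
    if (empty.n_elem > 0) {
      vec resid(P);
      for (uword p = 0; p < P; ++p) {
        vec r = X.col(p) - A.col(assign(p));
        resid(p) = dot(r, r);
      }
      uvec ord = sort_index(resid, "descend");
      for (uword e = 0; e < empty.n_elem && e < P; ++e) {
        A.col(empty(e)) = X.col(ord(e));
      }
      continue;
    }
    if (std::isfinite(prev) && prev - obj <= tol * std::max(prev, 1.0)) break;
    prev = obj;
    // exact update: component mean of the assigned pixels
    mat num(N, M, fill::zeros);
    vec den(M, fill::zeros);
    for (uword p = 0; p < P; ++p) {
      num.col(assign(p)) += X.col(p);
      den(assign(p)) += 1.0;
    }
    for (uword m = 0; m < M; ++m) {
      if (den(m) > 0) A.col(m) = num.col(m) / den(m);
    }
  }
  mat C(M, P, fill::zeros);
  for (uword p = 0; p < P; ++p) C(assign(p), p) = 1.0;
  return Rcpp::List::create(
    Rcpp::Named("basis") = A,
    Rcpp::Named("coefficients") = C,
    Rcpp::Named("objective") = obj);
}

// Variant of the polish with analog per-pixel amplitudes: each pixel gets
// its best single-atom nonnegative fit (a ray projection rather than a
// nearest centroid). More robust when the per-pixel magnitudes vary wildly
// (small kernel variances); the unit-coefficient variant is the faithful
// binary-model step. Both are exact alternating minimizers of their
// respective objectives.
// [[Rcpp::export]]
Rcpp::List polish_engine_analog(const arma::mat& X, const arma::mat& A0,
                                int iterations, double tol) {
  const uword N = X.n_rows, P = X.n_cols, M = A0.n_cols;
  mat A = A0;
  uvec assign(P, fill::zeros);
  vec cbest(P, fill::zeros);
  double prev = datum::inf, obj = datum::inf;
  const double x2 = accu(X % X);
  for (int it = 0; it < iterations; ++it) {
    vec a2 = sum(square(A), 0).t();
    a2.transform([](double v) { return v > 0 ? v : 1e-300; });
    mat AtX = A.t() * X;                     // M x P
    double explained = 0.0;
    for (uword p = 0; p < P; ++p) {
      double best = 0.0; uword bm = 0; double bc = 0.0;
      for (uword m = 0; m < M; ++m) {
        double c = AtX(m, p) / a2(m);
        if (c < 0) c = 0;
        double gain = c * (2.0 * AtX(m, p) - c * a2(m));
        if (gain > best) { best = gain; bm = m; bc = c; }
      }
      assign(p) = bm; cbest(p) = bc; explained += best;
    }
    obj = x2 - explained;
    uvec counts(M, fill::zeros);
    for (uword p = 0; p < P; ++p) if (cbest(p) > 0) counts(assign(p))++;
    uvec empty = find(counts == 0);
    if (empty.n_elem > 0) {
      vec resid(P);
      for (uword p = 0; p < P; ++p) {
        vec r = X.col(p) - A.col(assign(p)) * cbest(p);
        resid(p) = dot(r, r);
      }
      uvec ord = sort_index(resid, "descend");
      for (uword e = 0; e < empty.n_elem && e < P; ++e) {
        A.col(empty(e)) = X.col(ord(e));
      }
      continue;
    }
    if (std::isfinite(prev) && prev - obj <= tol * std::max(prev, 1.0)) break;
    prev = obj;
    mat num(N, M, fill::zeros);
    vec den(M, fill::zeros);
    for (uword p = 0; p < P; ++p) {
      if (cbest(p) <= 0) continue;
      num.col(assign(p)) += X.col(p) * cbest(p);
      den(assign(p)) += cbest(p) * cbest(p);
    }
    for (uword m = 0; m < M; ++m) {
      if (den(m) > 0) A.col(m) = num.col(m) / den(m);
    }
  }
  mat C(M, P, fill::zeros);
  for (uword p = 0; p < P; ++p) C(assign(p), p) = cbest(p);
  return Rcpp::List::create(
    Rcpp::Named("basis") = A,
    Rcpp::Named("coefficients") = C,
    Rcpp::Named("objective") = obj);
}

// [[Rcpp::export]]
arma::mat kernel_cross_cpp(const arma::mat& X, const arma::mat& anchors,
                           double sigma2) {
  // X: N x P pixels, anchors: D x N; result D x P
  mat G = anchors * X;                         // D x P
  vec a2 = sum(square(anchors), 1);
  rowvec x2 = sum(square(X), 0);
  G.each_col() -= 0.5 * a2;
  G.each_row() -= 0.5 * x2;
  G /= sigma2;                                 // -(|a|^2 + |x|^2 - 2 a.x)/(2 s2)
  return exp(G);
}
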