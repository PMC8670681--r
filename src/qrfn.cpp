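// Frisch-Newton interior-point solver for check-loss quantile regression.
//
// The primal problem min_b sum_k rho_tau(y_k - x_k' b) is solved through its
// bounded-variable dual
//     max_a  y'a   s.t.  X'a = (1 - tau) X'1,  0 <= a <= 1,
// with a Mehrotra predictor-corrector on a feasible starting point
// (a = (1-tau)1 satisfies the equality constraint exactly, and the dual
// start built from least-squares residuals satisfies dual feasibility
// exactly).  The Lagrange multiplier of the equality constraint is the
// vector of regression coefficients.
//
// Two entry points share the same iteration:
//   qrfn_cpp     - dense design matrix;
//   qrfn_fe_cpp  - design [Xd | unit dummies], where the dummy block is
//                  handled analytically through a Schur complement so the
//                  per-iteration cost stays linear in the number of
//                  observations (used by the pooled fixed-effects
//                  estimator, where the dummy block can have hundreds of
//                  columns).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double IP_DAMP = 0.9995;

// largest alpha >= 0 with v + alpha * dv >= 0 (Inf if unconstrained)
static double step_bound(const vec& v, const vec& dv) {
  double a = datum::inf;
  for (uword i = 0; i < v.n_elem; ++i)
    if (dv(i) < 0.0) a = std::min(a, -v(i) / dv(i));
  return a;
}

static vec sympd_solve(mat A, const vec& b, bool& ok) {
  vec out;
  ok = solve(out, A, b, solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok) {
    A.diag() += 1e-10 * (trace(A) / A.n_rows + 1.0);
    ok = solve(out, A, b);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List qrfn_cpp(const arma::mat& X, const arma::vec& y, double tau,
                    double eps = 1e-10, int maxit = 100) {
  const uword n = X.n_rows;
  const double nn = static_cast<double>(n);
  bool ok = true;

  vec x(n); x.fill(1.0 - tau);   // dual variable in [0, 1]
  vec s(n); s.fill(tau);         // slack 1 - x

  vec beta = sympd_solve(X.t() * X, X.t() * y, ok);
  vec r = y - X * beta;
  const double e0 = 1e-6 * (1.0 + norm(r, "inf"));
  vec w = clamp(r, 0.0, datum::inf) + e0;
  vec z = w - r;                 // w - z == r exactly, z, w > 0

  double gap = dot(z, x) + dot(w, s);
  const double tol = eps * (1.0 + accu(abs(y)));
  int it = 0;
  bool converged = gap < tol;

  while (!converged && it < maxit) {
    ++it;
    vec q = 1.0 / (z / x + w / s);
    mat M = X.t() * (X.each_col() % q);

    // affine (predictor) direction
    vec rhat = w - z;
    vec dbeta = sympd_solve(M, X.t() * (q % rhat), ok);
    if (!ok) break;
    vec dx = q % (rhat - X * dbeta);
    vec dz = -(z % (x + dx)) / x;
    vec dw = -(w % (s - dx)) / s;
    double ap = std::min(1.0, IP_DAMP * std::min(step_bound(x, dx), step_bound(s, -dx)));
    double ad = std::min(1.0, IP_DAMP * std::min(step_bound(z, dz), step_bound(w, dw)));

    // Mehrotra centering + corrector
    double mu = gap / (2.0 * nn);
    double gap_aff = dot(z + ad * dz, x + ap * dx) + dot(w + ad * dw, s - ap * dx);
    double sigma = std::pow(std::max(gap_aff, 0.0) / gap, 3.0);
    sigma = std::min(sigma, 1.0);
    double smu = sigma * mu;

    vec Nz = smu - x % z - dx % dz;
    vec Nw = smu - s % w + dx % dw;
    rhat = Nz / x - Nw / s;
    dbeta = sympd_solve(M, X.t() * (q % rhat), ok);
    if (!ok) break;
    dx = q % (rhat - X * dbeta);
    dz = (Nz - z % dx) / x;
    dw = (Nw + w % dx) / s;
    ap = std::min(1.0, IP_DAMP * std::min(step_bound(x, dx), step_bound(s, -dx)));
    ad = std::min(1.0, IP_DAMP * std::min(step_bound(z, dz), step_bound(w, dw)));

    x += ap * dx; s -= ap * dx;
    beta += ad * dbeta; z += ad * dz; w += ad * dw;
    gap = dot(z, x) + dot(w, s);
    converged = gap < tol;
  }

  return Rcpp::List::create(
    Rcpp::Named("coefficients") = beta,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("gap") = gap,
    Rcpp::Named("converged") = converged);
}

// Solve  M d = rhs  where M = [Xd Z]' diag(q) [Xd Z]  and Z is the unit-dummy
// block; returns the dense part in dbd and the dummy part in dbu.
static bool fe_block_solve(const mat& Xd, const uvec& unit, uword n_units,
                           const vec& q, const vec& v,
                           vec& dbd, vec& dbu) {
  const uword n = Xd.n_rows, md = Xd.n_cols;
  mat A11 = Xd.t() * (Xd.each_col() % q);
  mat B(md, n_units, fill::zeros);
  vec g(n_units, fill::zeros);
  vec r1(md, fill::zeros);
  vec r2(n_units, fill::zeros);
  for (uword k = 0; k < n; ++k) {
    const uword i = unit(k);
    g(i) += q(k);
    B.col(i) += q(k) * Xd.row(k).t();
    r2(i) += v(k);
  }
  r1 = Xd.t() * v;
  mat S = A11 - B * (B.each_row() / g.t()).t();
  bool ok;
  dbd = sympd_solve(S, r1 - B * (r2 / g), ok);
  if (!ok) return false;
  dbu = (r2 - B.t() * dbd) / g;
  return true;
}

// [[Rcpp::export]]
Rcpp::List qrfn_fe_cpp(const arma::mat& Xd, const arma::uvec& unit,
                       int n_units, const arma::vec& y, double tau,
                       double eps = 1e-10, int maxit = 100) {
  const uword n = Xd.n_rows, N = static_cast<uword>(n_units);
  const double nn = static_cast<double>(n);
  bool ok = true;

  vec x(n); x.fill(1.0 - tau);
  vec s(n); s.fill(tau);

  vec bd, bu;
  vec ones_q(n, fill::ones);
  ok = fe_block_solve(Xd, unit, N, ones_q, y, bd, bu);
  if (!ok) Rcpp::stop("singular fixed-effects design");
  vec fitted = Xd * bd + bu(unit);
  vec r = y - fitted;
  const double e0 = 1e-6 * (1.0 + norm(r, "inf"));
  vec w = clamp(r, 0.0, datum::inf) + e0;
  vec z = w - r;

  double gap = dot(z, x) + dot(w, s);
  const double tol = eps * (1.0 + accu(abs(y)));
  int it = 0;
  bool converged = gap < tol;

  while (!converged && it < maxit) {
    ++it;
    vec q = 1.0 / (z / x + w / s);

    vec rhat = w - z;
    vec dbd, dbu;
    if (!fe_block_solve(Xd, unit, N, q, q % rhat, dbd, dbu)) break;
    vec Xdb = Xd * dbd + dbu(unit);
    vec dx = q % (rhat - Xdb);
    vec dz = -(z % (x + dx)) / x;
    vec dw = -(w % (s - dx)) / s;
    double ap = std::min(1.0, IP_DAMP * std::min(step_bound(x, dx), step_bound(s, -dx)));
    double ad = std::min(1.0, IP_DAMP * std::min(step_bound(z, dz), step_bound(w, dw)));

    double mu = gap / (2.0 * nn);
    double gap_aff = dot(z + ad * dz, x + ap * dx) + dot(w + ad * dw, s - ap * dx);
    double sigma = std::pow(std::max(gap_aff, 0.0) / gap, 3.0);
    sigma = std::min(sigma, 1.0);
    double smu = sigma * mu;

    vec Nz = smu - x % z - dx % dz;
    vec Nw = smu - s % w + dx % dw;
    rhat = Nz / x - Nw / s;
    if (!fe_block_solve(Xd, unit, N, q, q % rhat, dbd, dbu)) break;
    Xdb = Xd * dbd + dbu(unit);
    dx = q % (rhat - Xdb);
    dz = (Nz - z % dx) / x;
    dw = (Nw + w % dx) / s;
    ap = std::min(1.0, IP_DAMP * std::min(step_bound(x, dx), step_bound(s, -dx)));
    ad = std::min(1.0, IP_DAMP * std::min(step_bound(z, dz), step_bound(w, dw)));

    x += ap * dx; s -= ap * dx;
    bd += ad * dbd; bu += ad * dbu;
    z += ad * dz; w += ad * dw;
    gap = dot(z, x) + dot(w, s);
    converged = gap < tol;
  }

  return Rcpp::List::create(
    Rcpp::Named("coefficients") = join_cols(bd, bu),
    Rcpp::Named("iterations") = it,
    Rcpp::Named("gap") = gap,
    Rcpp::Named("converged") = converged);
}
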