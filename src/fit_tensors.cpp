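// Batch per-voxel diffusion tensor estimation.
// Mirrors the single-voxel R reference (fit_tensor_wls / fit_tensor_robust):
// log-linear OLS init, WLS iterations with weights = squared predicted
// signals, and optionally Geman-McClure IRLS + residual-based outlier
// rejection with a final WLS refit on the retained measurements.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double robust_scale_cpp(const vec &r, double floor_ref) {
  double med = median(r);
  double mad = median(abs(r - med));
  double fl = 1e3 * datum::eps * std::max(std::abs(floor_ref), 1.0);
  return std::max(1.4826 * mad, fl);
}

// normalise and floor weights to keep the normal equations well
// conditioned under wildly inconsistent signals
static vec guard_weights(vec w) {
  w /= w.max();
  w.transform([](double x) { return x < 1e-10 ? 1e-10 : x; });
  return w;
}

static vec wls_iterate(const mat &X, const vec &y, vec beta, double tol,
                       int max_iter) {
  for (int it = 0; it < max_iter; ++it) {
    vec w = guard_weights(exp(2.0 * (X * beta)));
    mat Xw = X.each_col() % w;
    vec beta_new = solve(Xw.t() * X, Xw.t() * y, solve_opts::fast);
    double scale = std::max(abs(beta).max(), 1.0);
    bool conv = abs(beta_new - beta).max() <= tol * scale;
    beta = beta_new;
    if (conv) break;
  }
  return beta;
}

// [[Rcpp::export]]
Rcpp::List fit_tensors_batch(const arma::mat &signals, const arma::mat &X,
                             const arma::vec &bvals, bool robust,
                             double kappa, double tol, int max_iter,
                             double gm_tuning) {
  const uword m = X.n_rows, nvox = signals.n_cols;
  if (signals.n_rows != m) Rcpp::stop("signal/design row mismatch");
  mat beta_out(7, nvox);
  ivec fallback(nvox, fill::zeros), n_out(nvox, fill::zeros),
      clamped(nvox, fill::zeros);
  uvec is_b0 = find(bvals == 0.0);
  mat XtX = X.t() * X;

  for (uword v = 0; v < nvox; ++v) {
    vec s = signals.col(v);
    for (uword i = 0; i < m; ++i)
      if (!(s(i) > 0.0)) { s(i) = datum::eps; clamped(v) += 1; }
    vec y = log(s);
    vec beta = solve(XtX, X.t() * y, solve_opts::fast);
    if (!robust) {
      beta_out.col(v) = wls_iterate(X, y, beta, tol, max_iter);
      continue;
    }
    double smax = s.max();
    // robust scale from the initial plain-WLS fit's signal-scaled
    // residuals, held fixed through the IRLS (re-estimating it from the
    // redescending fit's own residuals collapses it when residual degrees
    // of freedom are few); sqrt(m/(m-p)) corrects the MAD for the fitted
    // parameters. Signal-scaled residuals share one noise sigma across
    // b-values, which log-domain residuals do not.
    {
      vec pred = X * beta;
      vec w = guard_weights(exp(2.0 * pred));
      mat Xw = X.each_col() % w;
      vec beta1 = solve(Xw.t() * X, Xw.t() * y, solve_opts::fast);
      vec pred1 = X * beta1;
      vec rs1 = (y - pred1) % exp(pred1);
      beta = beta1;
    }
    vec pred0 = X * beta;
    vec rs0 = (y - pred0) % exp(pred0);
    double sc = robust_scale_cpp(rs0, smax) *
                std::sqrt((double)m / (double)(m - X.n_cols));
    // stage 1: Geman-McClure IRLS at fixed scale
    for (int it = 0; it < max_iter; ++it) {
      vec pred = X * beta;
      vec pred_w = exp(2.0 * pred);
      vec rs = (y - pred) % exp(pred);
      vec gm = 1.0 / square(1.0 + square(rs / (gm_tuning * sc)));
      vec w = guard_weights(pred_w % gm);
      mat Xw = X.each_col() % w;
      vec beta_new = solve(Xw.t() * X, Xw.t() * y, solve_opts::fast);
      double scale = std::max(abs(beta).max(), 1.0);
      bool conv = abs(beta_new - beta).max() <= tol * scale;
      beta = beta_new;
      if (conv) break;
    }
    // stage 2: flag outliers; scale re-estimated once from the converged
    // robust fit's residuals so gross outliers cannot mask themselves
    vec pred = X * beta;
    vec rs = (y - pred) % exp(pred);
    double sc2 = robust_scale_cpp(rs, smax) *
                 std::sqrt((double)m / (double)(m - X.n_cols));
    uvec keep = find(abs(rs) <= kappa * sc2);
    n_out(v) = (int)(m - keep.n_elem);
    bool b0_kept = false;
    for (uword i = 0; i < keep.n_elem && !b0_kept; ++i)
      if (bvals(keep(i)) == 0.0) b0_kept = true;
    bool fb = keep.n_elem < 7 || !b0_kept;
    if (!fb) {
      mat Xk = X.rows(keep);
      double cn = cond(Xk);
      if (!std::isfinite(cn) || cn > 1e10) fb = true;
      else {
        vec yk = y(keep);
        vec bk = solve(Xk.t() * Xk, Xk.t() * yk, solve_opts::fast);
        beta_out.col(v) = wls_iterate(Xk, yk, bk, tol, max_iter);
      }
    }
    if (fb) {
      fallback(v) = 1;
      vec b2 = solve(XtX, X.t() * y, solve_opts::fast);
      beta_out.col(v) = wls_iterate(X, y, b2, tol, max_iter);
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta_out, Rcpp::Named("fallback") = fallback,
      Rcpp::Named("n_outliers") = n_out, Rcpp::Named("clamped") = clamped);
}

// Eigen decomposition of a whole tensor field: input nvox x 6 matrix of
// (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz); returns eigenvalues (descending), FA and
// the principal eigenvector per voxel.
// [[Rcpp::export]]
Rcpp::List eigen_field(const arma::mat &tensors) {
  const uword n = tensors.n_rows;
  mat evals(n, 3), v1(n, 3);
  vec fa(n);
  mat33 Dm;
  vec3 ev;
  mat33 evec;
  for (uword i = 0; i < n; ++i) {
    const double dxx = tensors(i, 0), dyy = tensors(i, 1), dzz = tensors(i, 2),
                 dxy = tensors(i, 3), dxz = tensors(i, 4), dyz = tensors(i, 5);
    if (!std::isfinite(dxx + dyy + dzz + dxy + dxz + dyz)) {
      evals.row(i).fill(datum::nan);
      v1.row(i).fill(datum::nan);
      fa(i) = datum::nan;
      continue;
    }
    Dm = {{dxx, dxy, dxz}, {dxy, dyy, dyz}, {dxz, dyz, dzz}};
    eig_sym(ev, evec, Dm);  // ascending
    evals(i, 0) = ev(2); evals(i, 1) = ev(1); evals(i, 2) = ev(0);
    double md = (ev(0) + ev(1) + ev(2)) / 3.0;
    double ss = dot(ev, ev);
    fa(i) = ss == 0.0 ? 0.0
                      : std::sqrt(1.5 * (std::pow(ev(0) - md, 2) +
                                         std::pow(ev(1) - md, 2) +
                                         std::pow(ev(2) - md, 2)) / ss);
    v1(i, 0) = evec(0, 2); v1(i, 1) = evec(1, 2); v1(i, 2) = evec(2, 2);
  }
  return Rcpp::List::create(Rcpp::Named("values") = evals,
                            Rcpp::Named("fa") = fa,
                            Rcpp::Named("v1") = v1);
}
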