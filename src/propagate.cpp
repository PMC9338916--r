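// Piecewise-constant linear-system propagation with eigendecomposition
// matrix exponentials. Lower-triangular 2x2 rate matrices (the
// absorption/elimination cascade) use the exact closed form of the EVD
// result, written with expm1 so it stays accurate through the confluent
// (equal-eigenvalue) limit. General matrices use eig_gen; when the
// eigenvector matrix is ill-conditioned (near-defective K) the step
// falls back to scaling-and-squaring.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// exp(dt * [[a, 0], [k, b]]): eigenvalues are a and b, and the (2,1)
// entry of the exponential is k (e^{a dt} - e^{b dt}) / (a - b),
// rewritten as k e^{b dt} expm1((a-b) dt) / (a-b) for stability.
static mat tri2_propagator(double a, double k, double b, double dt) {
  const double ea = std::exp(a * dt);
  const double eb = std::exp(b * dt);
  const double d = a - b;
  mat M(2, 2, fill::zeros);
  M(0, 0) = ea;
  M(1, 1) = eb;
  M(1, 0) = (d != 0.0) ? k * eb * std::expm1(d * dt) / d : k * dt * eb;
  return M;
}

static mat step_propagator(const mat& K, double dt, double cond_max) {
  if (K.n_rows == 2 && K(0, 1) == 0.0) {
    return tri2_propagator(K(0, 0), K(1, 0), K(1, 1), dt);
  }
  cx_vec eigval;
  cx_mat eigvec;
  bool ok = eig_gen(eigval, eigvec, K);
  if (ok) {
    double c = cond(eigvec);
    if (std::isfinite(c) && c <= cond_max) {
      cx_mat M = eigvec * diagmat(exp(eigval * dt)) * inv(eigvec);
      return real(M);
    }
  }
  return expmat(K * dt);
}

// [[Rcpp::export]]
arma::vec step_expm_cpp(const arma::mat& K, double dt, const arma::vec& state,
                        double cond_max) {
  return step_propagator(K, dt, cond_max) * state;
}

// Propagate y0 across a grid: one rate matrix per interval, exp(K_j dt_j)
// applied sequentially. Repeated (K, dt) pairs reuse the previous
// propagator, so constant-K stretches cost one decomposition.
// [[Rcpp::export]]
arma::mat propagate_cpp(const arma::cube& Ks, const arma::vec& dts,
                        const arma::vec& y0, double cond_max) {
  const uword m = y0.n_elem;
  const uword n = dts.n_elem;
  if (Ks.n_slices != n || Ks.n_rows != m || Ks.n_cols != m) {
    Rcpp::stop("need one m x m rate matrix per grid interval");
  }
  mat traj(m, n + 1);
  traj.col(0) = y0;
  mat M, K_prev;
  double dt_prev = std::numeric_limits<double>::quiet_NaN();
  bool have = false;
  for (uword j = 0; j < n; ++j) {
    const mat K = Ks.slice(j);
    bool reuse = have && dts(j) == dt_prev &&
                 approx_equal(K, K_prev, "absdiff", 0.0);
    if (!reuse) {
      M = step_propagator(K, dts(j), cond_max);
      K_prev = K;
      dt_prev = dts(j);
      have = true;
    }
    traj.col(j + 1) = M * traj.col(j);
  }
  return traj;
}
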