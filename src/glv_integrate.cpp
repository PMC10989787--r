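// Fixed-step RK4 integrator for clamped generalized Lotka-Volterra dynamics.
// Clamped coordinates are held constant (zero derivative, value reset each
// step); negative excursions are floored at zero.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec glv_deriv(const vec& x, const vec& r, const mat& A,
                            const uvec& clamp_idx) {
  vec d = x % (r + A * x);
  if (clamp_idx.n_elem > 0) d.elem(clamp_idx).zeros();
  return d;
}

// [[Rcpp::export]]
Rcpp::List glv_integrate_cpp(arma::vec x0, arma::vec r, arma::mat A,
                             arma::ivec clamp_idx0, arma::vec clamp_val,
                             double dt, double t_max, double tol,
                             double overflow, int record_every) {
  uvec clamp_idx;
  if (clamp_idx0.n_elem > 0) {
    clamp_idx = conv_to<uvec>::from(clamp_idx0);
  }
  vec x = x0;
  if (clamp_idx.n_elem > 0) x.elem(clamp_idx) = clamp_val;

  const int n_steps = (int) std::ceil(t_max / dt);
  std::vector<double> times;
  std::vector<vec> snaps;
  times.push_back(0.0);
  snaps.push_back(x);

  bool converged = false, diverged = false;
  double t = 0.0;
  int step = 0;
  for (step = 0; step < n_steps; ++step) {
    vec k1 = glv_deriv(x, r, A, clamp_idx);
    if (k1.is_empty() || max(abs(k1)) < tol) { converged = true; break; }
    vec k2 = glv_deriv(clamp(x + 0.5 * dt * k1, 0.0, datum::inf), r, A,
                       clamp_idx);
    vec k3 = glv_deriv(clamp(x + 0.5 * dt * k2, 0.0, datum::inf), r, A,
                       clamp_idx);
    vec k4 = glv_deriv(clamp(x + dt * k3, 0.0, datum::inf), r, A, clamp_idx);
    x += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    x = clamp(x, 0.0, datum::inf);
    if (clamp_idx.n_elem > 0) x.elem(clamp_idx) = clamp_val;
    t += dt;
    if (x.has_nan() || max(abs(x)) > overflow) { diverged = true; break; }
    if ((step + 1) % record_every == 0) {
      times.push_back(t);
      snaps.push_back(x);
    }
  }
  if (!diverged && !converged) {
    vec d = glv_deriv(x, r, A, clamp_idx);
    converged = d.is_empty() || max(abs(d)) < tol;
  }
  if (times.back() != t) {
    times.push_back(t);
    snaps.push_back(x);
  }
  mat traj(snaps.size(), x.n_elem);
  for (size_t i = 0; i < snaps.size(); ++i) traj.row(i) = snaps[i].t();

  return Rcpp::List::create(
      Rcpp::Named("state") = x,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("diverged") = diverged,
      Rcpp::Named("t_end") = t,
      Rcpp::Named("times") = times,
      Rcpp::Named("trajectory") = traj);
}
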