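// Fast batch evaluation of mean-field averages (adaptability, precision)
// for mirror-symmetric metaplastic models.  Used by the stochastic
// frontier optimizer, where millions of small models are scored; the R
// implementation in meanfield.R is the reference and the two are tested
// for agreement.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double kUnitGapTol = 1e-8;

// Fill the potentiation matrix from the free-rate vector (source-major
// order over pairs i<j, matching rate_index() on the R side), set stay
// probabilities as the diagonal remainder, and build the mirrored
// depression matrix.  Returns false if any source outflow exceeds 1 or a
// rate is negative.
bool build_matrices(const rowvec& params, int n, mat& pot, mat& dep) {
  pot.zeros(n, n);
  int k = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double r = params(k++);
      if (r < 0.0) return false;
      pot(j, i) = r;
    }
  }
  for (int i = 0; i < n; ++i) {
    double out = accu(pot.col(i));
    if (out > 1.0 + 1e-12) return false;
    pot(i, i) = 1.0 - out;
  }
  dep.set_size(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = 0; b < n; ++b) {
      dep(a, b) = pot(n - 1 - a, n - 1 - b);
    }
  }
  return true;
}

// Stationary distribution of a column-stochastic matrix via a bordered
// solve; returns false on failure.
bool stationary(const mat& tbar, vec& psi) {
  int n = tbar.n_rows;
  mat b = tbar - eye(n, n);
  b.row(n - 1).ones();
  vec rhs = zeros<vec>(n);
  rhs(n - 1) = 1.0;
  bool ok = solve(psi, b, rhs, solve_opts::no_approx);
  if (!ok) return false;
  if (psi.min() < -1e-9) return false;
  psi = clamp(psi, 0.0, datum::inf);
  double s = accu(psi);
  if (s <= 0) return false;
  psi /= s;
  return true;
}

double signal_of(const vec& psi, const vec& eff) { return dot(psi, eff); }

// Mean-field evaluation of one model over the grid.  Returns {avgA, avgP}
// or NaNs when the model is invalid or degenerate anywhere on the grid.
rowvec eval_model(const rowvec& params, int n, const vec& grid,
                  double step) {
  rowvec bad = {datum::nan, datum::nan};
  mat pot, dep;
  if (!build_matrices(params, n, pot, dep)) return bad;
  vec eff(n);
  for (int i = 0; i < n; ++i) eff(i) = (i < n / 2) ? -1.0 : 1.0;

  double sum_a = 0.0, sum_p = 0.0;
  vec psi, psi_lo, psi_hi;
  for (uword g = 0; g < grid.n_elem; ++g) {
    double pr = grid(g);
    mat tbar = pr * pot + (1.0 - pr) * dep;
    cx_vec ev;
    if (!eig_gen(ev, tbar)) return bad;
    vec mods = sort(abs(ev), "descend");
    if (mods.n_elem < 2 || mods(1) > 1.0 - kUnitGapTol) return bad;
    double a = 1.0 - mods(1);
    if (!stationary(tbar, psi)) return bad;
    double s = signal_of(psi, eff);
    double s_pot = signal_of(pot * psi, eff);
    double s_dep = signal_of(dep * psi, eff);
    double eta = pr * std::abs(s - s_pot) + (1.0 - pr) * std::abs(s - s_dep);
    if (eta <= 0) return bad;
    double lo = pr - step, hi = pr + step;
    if (lo < 0 || hi > 1) return bad;
    mat t_lo = lo * pot + (1.0 - lo) * dep;
    mat t_hi = hi * pot + (1.0 - hi) * dep;
    if (!stationary(t_lo, psi_lo) || !stationary(t_hi, psi_hi)) return bad;
    double sens =
        (signal_of(psi_hi, eff) - signal_of(psi_lo, eff)) / (hi - lo);
    sum_a += a;
    sum_p += sens / eta;
  }
  rowvec out = {sum_a / grid.n_elem, sum_p / grid.n_elem};
  return out;
}

}  // namespace

// [[Rcpp::export]]
arma::mat mf_batch_cpp(const arma::mat& params, int n_states,
                       const arma::vec& p_r_grid, double step) {
  mat out(params.n_rows, 2);
  for (uword s = 0; s < params.n_rows; ++s) {
    out.row(s) = eval_model(params.row(s), n_states, p_r_grid, step);
  }
  return out;
}
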