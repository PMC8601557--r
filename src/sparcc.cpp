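// SparCC inner loop: Dirichlet-posterior resampling, variation matrix,
// basis-variance solve with iterative exclusion of strongly correlated
// pairs, averaged over inference iterations. Uses R's RNG so results are
// reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Solve the basis-variance system for one variation matrix T, excluding up
// to `rounds` pairs whose |rho| exceeds `thr` (sparsity repair).
static arma::mat basis_correlation(const arma::mat& T, double thr,
                                   int rounds, bool& negvar) {
  const arma::uword D = T.n_rows;
  arma::mat active(D, D, arma::fill::ones);
  active.diag().zeros();
  arma::mat rho(D, D, arma::fill::zeros);
  int excluded = 0;
  for (;;) {
    arma::mat A = active;
    A.diag() = arma::sum(active, 1);
    arma::vec ti = arma::sum(T % active, 1);
    arma::vec w;
    // exclusions can make the system singular; fall back to the
    // minimum-norm solution rather than failing
    if (!arma::solve(w, A, ti, arma::solve_opts::no_approx))
      w = arma::pinv(A) * ti;
    if (w.min() <= 0.0) {
      negvar = true;
      w.transform([](double v) { return v <= 0.0 ? 1e-6 : v; });
    }
    arma::vec sw = arma::sqrt(w);
    rho = arma::repmat(w, 1, D);
    rho += arma::repmat(w.t(), D, 1);
    rho -= T;
    rho /= 2.0 * (sw * sw.t());
    rho = arma::clamp(rho, -1.0, 1.0);
    rho.diag().ones();
    if (excluded >= rounds) break;
    arma::mat cand = arma::abs(rho) % active;
    cand.diag().zeros();
    arma::uword idx = cand.index_max();
    if (cand(idx) <= thr) break;
    arma::uword i = idx % D, j = idx / D;
    active(i, j) = 0.0;
    active(j, i) = 0.0;
    ++excluded;
  }
  return rho;
}

// [[Rcpp::export(name = ".sparccRhoCpp")]]
List sparcc_rho_cpp(const arma::mat& counts, int n_iterations,
                    double threshold, int rounds) {
  const arma::uword n = counts.n_rows, D = counts.n_cols;
  arma::mat acc(D, D, arma::fill::zeros);
  bool negvar = false;
  for (int it = 0; it < n_iterations; ++it) {
    arma::mat x(n, D);
    for (arma::uword j = 0; j < D; ++j)
      for (arma::uword i = 0; i < n; ++i)
        x(i, j) = R::rgamma(counts(i, j), 1.0);
    x.each_col() /= arma::sum(x, 1);
    arma::mat L = arma::log(x);
    arma::mat cv = arma::cov(L);
    arma::vec v = cv.diag();
    arma::mat T = arma::repmat(v, 1, D) + arma::repmat(v.t(), D, 1) - 2.0 * cv;
    acc += basis_correlation(T, threshold, rounds, negvar);
  }
  arma::mat rho = acc / n_iterations;
  rho = (rho + rho.t()) / 2.0;
  rho.diag().ones();
  return List::create(_["rho"] = rho, _["negvar"] = negvar);
}
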