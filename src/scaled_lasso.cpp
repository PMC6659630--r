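#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// Cyclic coordinate descent for the lasso on a standardized design
// (columns mean-zero with mean square one):
//   minimize ||y - X b||^2 / (2n) + lam * ||b||_1
// r = y - X b and b are updated in place. `skip` (-1 for none) freezes one
// column at zero so a predictor can be excluded without copying the design.
// Coordinates are visited in ascending column order so fits are reproducible.
static void cd_lasso(const mat& X, vec& r, vec& b, double lam, int skip,
                     double tol, int max_sweep) {
  const int k = X.n_cols;
  const double n = (double) X.n_rows;
  for (int sweep = 0; sweep < max_sweep; ++sweep) {
    double maxdel = 0.0;
    for (int j = 0; j < k; ++j) {
      if (j == skip) continue;
      const double bj = b[j];
      const double rho = dot(X.unsafe_col(j), r) / n + bj;
      double bnew;
      if (rho > lam)       bnew = rho - lam;
      else if (rho < -lam) bnew = rho + lam;
      else                 bnew = 0.0;
      const double del = bnew - bj;
      if (del != 0.0) {
        r -= del * X.unsafe_col(j);
        b[j] = bnew;
        const double adel = std::fabs(del);
        if (adel > maxdel) maxdel = adel;
      }
    }
    if (maxdel < tol) break;
  }
}

// Alternating scaled-lasso iterations on (b, sigma), warm started from the
// incoming (r, b, sigma). Converges on |delta sigma| < tol.
static int scaled_lasso_core(const mat& X, vec& r, vec& b, double& sigma,
                             double lambda0, int skip, double tol,
                             int max_iter) {
  const double n = (double) X.n_rows;
  int it = 0;
  while (it < max_iter) {
    ++it;
    const double lam = sigma * lambda0;
    cd_lasso(X, r, b, lam, skip, 1e-9, 1000);
    double signew = std::sqrt(dot(r, r) / n);
    if (signew < 1e-12) signew = 1e-12;
    const double del = std::fabs(signew - sigma);
    sigma = signew;
    if (del < tol) break;
  }
  return it;
}

// [[Rcpp::export]]
List cpp_scaled_lasso(const arma::mat& X, const arma::vec& y, double lambda0,
                      double tol, int max_iter) {
  vec b(X.n_cols, fill::zeros);
  vec r = y;
  double sigma = std::sqrt(dot(y, y) / (double) X.n_rows);
  int it = 0;
  if (sigma > 1e-12 && X.n_cols > 0) {
    it = scaled_lasso_core(X, r, b, sigma, lambda0, -1, tol, max_iter);
  }
  return List::create(_["beta"] = b, _["sigma"] = sigma,
                      _["residuals"] = r, _["n_iter"] = it);
}

// Node-wise regressions: column i of Xs regressed on all remaining columns.
// Returns the n x p residual matrix and the p noise levels.
// [[Rcpp::export]]
List cpp_ggm_nodewise(const arma::mat& Xs, double lambda0, double tol,
                      int max_iter) {
  const int n = Xs.n_rows, p = Xs.n_cols;
  mat E(n, p);
  vec sig(p);
  mat D(n, p - 1);
  for (int i = 0; i < p; ++i) {
    int c = 0;
    for (int j = 0; j < p; ++j) if (j != i) D.col(c++) = Xs.col(j);
    vec y = Xs.col(i);
    vec b(p - 1, fill::zeros);
    vec r = y;
    double sigma = std::sqrt(dot(y, y) / (double) n);
    if (sigma > 1e-12)
      scaled_lasso_core(D, r, b, sigma, lambda0, -1, tol, max_iter);
    E.col(i) = r;
    sig[i] = sigma;
  }
  return List::create(_["residuals"] = E, _["sigma"] = sig);
}

// Pairwise construction: for each unordered pair {i, j}, both columns are
// regressed on the remaining p - 2 columns and the 2x2 residual Gram matrix
// is inverted. The full node-wise fit of column i warm-starts each
// single-column exclusion; dropping an inactive predictor leaves the
// stationary point unchanged, so only active exclusions are refit.
// Returns the symmetric off-diagonal estimates, the per-pair diagonal
// estimates dpair (dpair(a, b) = pair {a,b}'s estimate of omega_aa), and a
// flag matrix for pairs whose residual Gram was numerically singular.
// [[Rcpp::export]]
List cpp_ggm_pairwise(const arma::mat& Xs, double lambda0, double tol,
                      int max_iter) {
  const int n = Xs.n_rows, p = Xs.n_cols;
  cube Rex(n, p, p);  // Rex.slice(i).col(j): residual of i on all but {i, j}
  mat D(n, p - 1);
  ivec map(p - 1);
  for (int i = 0; i < p; ++i) {
    int c = 0;
    for (int j = 0; j < p; ++j) if (j != i) { D.col(c) = Xs.col(j); map[c++] = j; }
    vec y = Xs.col(i);
    vec b0(p - 1, fill::zeros);
    vec r0 = y;
    double sig0 = std::sqrt(dot(y, y) / (double) n);
    if (sig0 > 1e-12)
      scaled_lasso_core(D, r0, b0, sig0, lambda0, -1, tol, max_iter);
    for (int c2 = 0; c2 < p - 1; ++c2) {
      const int j = map[c2];
      if (b0[c2] == 0.0) {
        Rex.slice(i).col(j) = r0;
      } else {
        vec b = b0;
        vec r = r0 + b[c2] * D.col(c2);
        b[c2] = 0.0;
        double sigma = sig0;
        scaled_lasso_core(D, r, b, sigma, lambda0, c2, tol, max_iter);
        Rex.slice(i).col(j) = r;
      }
    }
  }
  mat omega(p, p, fill::zeros), dpair(p, p, fill::zeros);
  umat bad(p, p, fill::zeros);
  const double dn = (double) n;
  for (int i = 0; i < p - 1; ++i) {
    for (int j = i + 1; j < p; ++j) {
      vec ei = Rex.slice(i).col(j);
      vec ej = Rex.slice(j).col(i);
      const double a  = dot(ei, ei) / dn;
      const double bb = dot(ei, ej) / dn;
      const double cc = dot(ej, ej) / dn;
      const double det = a * cc - bb * bb;
      if (det <= 1e-12) {
        bad(i, j) = bad(j, i) = 1;
        continue;
      }
      omega(i, j) = omega(j, i) = -bb / det;
      dpair(i, j) = cc / det;
      dpair(j, i) = a / det;
    }
  }
  return List::create(_["omega"] = omega, _["dpair"] = dpair, _["bad"] = bad);
}
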