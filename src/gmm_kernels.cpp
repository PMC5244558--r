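// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Multivariate normal log-densities for every point under every mixture
// component. X is n x d, means K x d, covs d x d x K. Returns n x K.
// Cholesky factorisation per component; a non-PD covariance is an error
// (callers regularise after every M-step).
// [[Rcpp::export(name = ".gmm_log_density")]]
arma::mat gmm_log_density(const arma::mat& X,
                          const arma::mat& means,
                          const arma::cube& covs) {
  const arma::uword n = X.n_rows, d = X.n_cols, K = means.n_rows;
  arma::mat out(n, K);
  const double cst = -0.5 * d * std::log(2.0 * M_PI);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat L;
    if (!arma::chol(L, covs.slice(k), "lower")) {
      stop("covariance matrix of component %d is not positive definite", k + 1);
    }
    double logdet = arma::sum(arma::log(L.diag()));
    arma::mat Xc = X.each_row() - means.row(k);
    // solve L * y = Xc' -> quadratic form = colSums(y^2)
    arma::mat Y = arma::solve(arma::trimatl(L), Xc.t());
    out.col(k) = cst - logdet - 0.5 * arma::sum(arma::square(Y), 0).t();
  }
  return out;
}

// Weighted M-step statistics: given responsibilities R (n x K) and data X
// (n x d), returns component counts, means and covariances in one pass.
// [[Rcpp::export(name = ".gmm_mstep")]]
List gmm_mstep(const arma::mat& X, const arma::mat& R, double reg) {
  const arma::uword d = X.n_cols, K = R.n_cols;
  arma::vec Nk = arma::sum(R, 0).t();
  arma::mat M(K, d);
  arma::cube S(d, d, K);
  for (arma::uword k = 0; k < K; ++k) {
    arma::vec r = R.col(k);
    arma::rowvec mu = (r.t() * X) / Nk(k);
    M.row(k) = mu;
    arma::mat Xc = X.each_row() - mu;
    Xc.each_col() %= arma::sqrt(r);
    S.slice(k) = (Xc.t() * Xc) / Nk(k) + reg * arma::eye(d, d);
  }
  return List::create(_["counts"] = Nk, _["means"] = M, _["covs"] = S);
}
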