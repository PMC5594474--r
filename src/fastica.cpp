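#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// W <- (W W^T)^{-1/2} W (symmetric decorrelation)
static mat sym_decorrelate(const mat& W) {
  vec eigval;
  mat eigvec;
  eig_sym(eigval, eigvec, W * W.t());
  eigval = clamp(eigval, datum::eps, datum::inf);
  return eigvec * diagmat(1.0 / sqrt(eigval)) * eigvec.t() * W;
}

// Symmetric (parallel) fastICA fixed point with the pow3 contrast on a
// whitened M x N matrix Z, starting from the rotation W0. Convergence is
// the usual criterion: the largest deviation of |diag(W_new W_old^T)|
// from 1 must fall below tol.
// [[Rcpp::export(name = ".fastica_pow3_core")]]
Rcpp::List fastica_pow3_core(const arma::mat& Z, const arma::mat& W0, double tol,
                             int max_iter) {
  const double N = static_cast<double>(Z.n_cols);
  mat W = sym_decorrelate(W0);
  bool converged = false;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    mat U = W * Z;
    mat U2 = square(U);
    // E[z g(u)] - E[g'(u)] w  with g(u) = u^3, g'(u) = 3 u^2
    mat W1 = ((U % U2) * Z.t()) / N - diagmat(3.0 * mean(U2, 1)) * W;
    W1 = sym_decorrelate(W1);
    const double delta = (arma::abs(arma::abs(sum(W1 % W, 1)) - 1.0)).max();
    W = W1;
    if (delta < tol) {
      converged = true;
      break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("iterations") = iter);
}
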