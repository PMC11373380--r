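// Smooth acyclicity function and penalized least-squares objective for the
// continuous DAG-learning program.  W is d x d with the "row causes column"
// convention: X = X W + E.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// h(W) = trace(exp(W o W)) - d, gradient = exp(W o W)^T o 2W.
// h is zero exactly when the support of W is acyclic.
// [[Rcpp::export(name = ".acyclicity_h_cpp")]]
List acyclicity_h_cpp(const arma::mat& W) {
  const arma::uword d = W.n_rows;
  arma::mat E = arma::expmat(W % W);
  double h = arma::trace(E) - static_cast<double>(d);
  arma::mat grad = E.t() % (2.0 * W);
  return List::create(Named("value") = h, Named("gradient") = grad);
}

// Augmented-Lagrangian objective and gradient over the split free variables
// w = c(w_plus, w_minus), W[free] = w_plus - w_minus, all other entries 0.
//
//   F = 0.5 * tr((I-W)' S (I-W)) + lambda1 * sum(w) + 0.5*rho*h^2 + alpha*h
//
// S = X'X / n is precomputed once per fit; free_idx are 0-based column-major
// indices into W.
// [[Rcpp::export(name = ".notears_obj_cpp")]]
List notears_obj_cpp(const arma::vec& w, const arma::uvec& free_idx,
                     const arma::mat& S, double lambda1, double rho,
                     double alpha) {
  const arma::uword d = S.n_rows;
  const arma::uword m = free_idx.n_elem;
  arma::mat W(d, d, arma::fill::zeros);
  for (arma::uword k = 0; k < m; ++k)
    W(free_idx(k)) = w(k) - w(k + m);

  arma::mat ImW = arma::eye(d, d) - W;
  arma::mat SImW = S * ImW;
  double loss = 0.5 * arma::accu(ImW % SImW);
  arma::mat loss_grad = -SImW;  // d loss / d W

  arma::mat E = arma::expmat(W % W);
  double h = arma::trace(E) - static_cast<double>(d);
  arma::mat h_grad = E.t() % (2.0 * W);

  double value = loss + lambda1 * arma::accu(w) + 0.5 * rho * h * h + alpha * h;
  arma::mat G = loss_grad + (rho * h + alpha) * h_grad;

  arma::vec grad(2 * m);
  for (arma::uword k = 0; k < m; ++k) {
    double g = G(free_idx(k));
    grad(k) = g + lambda1;
    grad(k + m) = -g + lambda1;
  }
  return List::create(Named("value") = value, Named("grad") = grad,
                      Named("h") = h);
}
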