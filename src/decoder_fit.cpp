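// Ridge-penalized logistic regression by iteratively reweighted least
// squares, plus k-fold cross-validated penalty selection. Hot path of the
// population decoder: called once per unit, class, and repeat.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// X includes the intercept column (first); the intercept is unpenalized.
static vec irls(const mat& X, const vec& y, double lambda, int max_iter,
                double tol) {
  const uword p = X.n_cols;
  if (!std::isfinite(lambda)) {
    // infinite penalty: intercept-only (null) model predicting the prior
    vec b(p, fill::zeros);
    double mu = std::min(std::max(mean(y), 1e-12), 1.0 - 1e-12);
    b(0) = std::log(mu / (1.0 - mu));
    return b;
  }
  vec pen(p);
  pen.fill(lambda);
  pen(0) = 0.0;
  vec b(p, fill::zeros);
  for (int it = 0; it < max_iter; ++it) {
    vec eta = X * b;
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    vec z = eta + (y - mu) / w;
    mat A = X.t() * (X.each_col() % w);
    A.diag() += pen;
    vec bn;
    if (!solve(bn, A, X.t() * (w % z), solve_opts::likely_sympd))
      break;
    if (max(abs(bn - b)) < tol) {
      b = bn;
      break;
    }
    b = bn;
  }
  return b;
}

// [[Rcpp::export]]
arma::vec ridge_logistic_cpp(const arma::mat& X, const arma::vec& y,
                             double lambda, int max_iter = 30,
                             double tol = 1e-8) {
  return irls(X, y, lambda, max_iter, tol);
}

// foldid: 1..k per observation. Selects lambda by summed held-out binomial
// deviance, then refits on all observations at the chosen penalty.
// [[Rcpp::export]]
arma::vec cv_ridge_logistic_cpp(const arma::mat& X, const arma::vec& y,
                                const arma::vec& lambdas,
                                const arma::ivec& foldid, int max_iter = 30,
                                double tol = 1e-8) {
  const int k = foldid.max();
  vec dev(lambdas.n_elem, fill::zeros);
  for (uword li = 0; li < lambdas.n_elem; ++li) {
    for (int f = 1; f <= k; ++f) {
      uvec tr = find(foldid != f);
      uvec te = find(foldid == f);
      if (tr.is_empty() || te.is_empty()) continue;
      vec b = irls(X.rows(tr), y.elem(tr), lambdas(li), max_iter, tol);
      vec mu = 1.0 / (1.0 + exp(-(X.rows(te) * b)));
      mu = clamp(mu, 1e-12, 1.0 - 1e-12);
      dev(li) += -2.0 * sum(y.elem(te) % log(mu) +
                            (1.0 - y.elem(te)) % log(1.0 - mu));
    }
  }
  return irls(X, y, lambdas(dev.index_min()), max_iter, tol);
}
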