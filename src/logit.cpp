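// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Newton-Raphson (IRLS) for binary logistic regression.
// X includes the intercept column. Returns MLE, Wald SEs, log-likelihood
// and convergence/separation diagnostics.
// [[Rcpp::export]]
List logit_irls_cpp(const arma::mat& X, const arma::vec& y,
                    double tol = 1e-8, int maxit = 50) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  double ll_old = -std::numeric_limits<double>::infinity();
  bool converged = false;
  bool singular = false;
  double ll = ll_old;

  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    // log-likelihood, guarded against log(0)
    arma::vec mu_c = arma::clamp(mu, 1e-12, 1.0 - 1e-12);
    ll = arma::accu(y % arma::log(mu_c) + (1.0 - y) % arma::log(1.0 - mu_c));
    arma::vec w = mu % (1.0 - mu);
    arma::mat XtWX = X.t() * (X.each_col() % w);
    arma::vec score = X.t() * (y - mu);
    arma::vec step;
    bool ok = arma::solve(step, XtWX, score, arma::solve_opts::no_approx);
    if (!ok) { singular = true; break; }
    // step-halving if the likelihood would not improve
    double step_scale = 1.0;
    arma::vec beta_new = beta + step;
    for (int h = 0; h < 20; ++h) {
      arma::vec eta_n = X * beta_new;
      arma::vec mu_n = arma::clamp(1.0 / (1.0 + arma::exp(-eta_n)), 1e-12, 1.0 - 1e-12);
      double ll_n = arma::accu(y % arma::log(mu_n) + (1.0 - y) % arma::log(1.0 - mu_n));
      if (std::isfinite(ll_n) && ll_n >= ll - 1e-10) { break; }
      step_scale *= 0.5;
      beta_new = beta + step_scale * step;
    }
    beta = beta_new;
    if (std::fabs(ll - ll_old) < tol && arma::norm(step * step_scale, "inf") < 1e-6) {
      converged = true;
      break;
    }
    ll_old = ll;
  }

  arma::vec eta = X * beta;
  arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
  arma::vec w = mu % (1.0 - mu);
  arma::mat XtWX = X.t() * (X.each_col() % w);
  arma::vec se(p);
  arma::mat cov;
  bool inv_ok = arma::inv_sympd(cov, XtWX);
  if (inv_ok) {
    se = arma::sqrt(cov.diag());
  } else {
    se.fill(NA_REAL);
    singular = true;
  }
  arma::vec mu_c = arma::clamp(mu, 1e-12, 1.0 - 1e-12);
  ll = arma::accu(y % arma::log(mu_c) + (1.0 - y) % arma::log(1.0 - mu_c));
  // crude but effective separation heuristic: exploding coefficients
  bool separated = arma::norm(beta, "inf") > 15.0;

  return List::create(_["coefficients"] = beta,
                      _["se"] = se,
                      _["loglik"] = ll,
                      _["fitted"] = mu,
                      _["converged"] = converged,
                      _["singular"] = singular,
                      _["separated"] = separated);
}
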