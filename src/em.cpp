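#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One EM run for a Gaussian mixture with class-specific means, variances
// shared across classes, and zero covariance between indicators.
// Log-space density accumulation with a row-wise log-sum-exp so small
// responsibilities never underflow.
//
// Convergence: stop when the log-likelihood improves by less than `tol`.
// A component whose mixing weight falls below `empty_tol` marks the run
// degenerate; the caller (multi-start) discards it.
// [[Rcpp::export]]
List em_fit_cpp(const arma::mat &X, arma::vec pi, arma::mat mu,
                arma::vec sigma2, double tol, int max_iter,
                double var_floor, double empty_tol) {
  const arma::uword n = X.n_rows, p = X.n_cols, K = pi.n_elem;
  arma::mat logdens(n, K), post(n, K);
  std::vector<double> trace;
  trace.reserve(64);
  double ll = -arma::datum::inf;
  bool degenerate = false, converged = false, floored = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // E-step: log f(x_i | class k) + log pi_k, indicator-wise (diagonal model)
    for (arma::uword k = 0; k < K; ++k) {
      arma::vec acc(n, arma::fill::zeros);
      for (arma::uword j = 0; j < p; ++j) {
        const double s2 = sigma2(j);
        const arma::vec d = X.col(j) - mu(k, j);
        acc += -0.5 * std::log(2.0 * arma::datum::pi * s2) -
               arma::square(d) / (2.0 * s2);
      }
      logdens.col(k) = acc + std::log(pi(k));
    }
    arma::vec m = arma::max(logdens, 1);
    arma::vec lse = m + arma::log(arma::sum(arma::exp(logdens.each_col() - m), 1));
    const double newll = arma::accu(lse);
    post = arma::exp(logdens.each_col() - lse);
    trace.push_back(newll);
    if (iter > 0 && newll - ll < tol) {
      ll = newll;
      converged = true;
      break;
    }
    ll = newll;

    // M-step
    arma::rowvec nk = arma::sum(post, 0);
    pi = nk.t() / static_cast<double>(n);
    if (pi.min() < empty_tol) {
      degenerate = true;
      break;
    }
    mu = post.t() * X;
    mu.each_col() /= nk.t();
    for (arma::uword j = 0; j < p; ++j) {
      double s = 0.0;
      for (arma::uword k = 0; k < K; ++k) {
        const arma::vec d = X.col(j) - mu(k, j);
        s += arma::dot(post.col(k), arma::square(d));
      }
      s /= static_cast<double>(n);
      if (s < var_floor) {
        s = var_floor;
        floored = true;
      }
      sigma2(j) = s;
    }
  }

  if (!degenerate && !converged) {
    // hit max_iter after an M-step: refresh ll/posterior for the final params
    for (arma::uword k = 0; k < K; ++k) {
      arma::vec acc(n, arma::fill::zeros);
      for (arma::uword j = 0; j < p; ++j) {
        const double s2 = sigma2(j);
        const arma::vec d = X.col(j) - mu(k, j);
        acc += -0.5 * std::log(2.0 * arma::datum::pi * s2) -
               arma::square(d) / (2.0 * s2);
      }
      logdens.col(k) = acc + std::log(pi(k));
    }
    arma::vec m = arma::max(logdens, 1);
    arma::vec lse = m + arma::log(arma::sum(arma::exp(logdens.each_col() - m), 1));
    ll = arma::accu(lse);
    post = arma::exp(logdens.each_col() - lse);
    trace.push_back(ll);
  }

  return List::create(
      _["weights"] = pi, _["means"] = mu, _["variances"] = sigma2,
      _["loglik"] = ll, _["posterior"] = post,
      _["trace"] = NumericVector(trace.begin(), trace.end()),
      _["iterations"] = iter, _["converged"] = converged,
      _["degenerate"] = degenerate, _["variance_floored"] = floored);
}
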