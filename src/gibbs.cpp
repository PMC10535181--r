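// Gibbs sampler for per-compound Bayesian linear regression.
//
// Three prior forms are supported:
//   "independent": beta_j ~ N(m_j, s_j^2) independently of the noise variance,
//                  sigma2 ~ InvGamma(shape, rate).  Semi-conjugate; this is the
//                  default weakly-informative configuration.
//   "nig":         beta | sigma2 ~ N(m, sigma2 * diag(s^2)),
//                  sigma2 ~ InvGamma(shape, rate).  Fully conjugate
//                  normal-inverse-gamma; admits the exact analytic posterior
//                  used as the testing oracle.
//   "known":       sigma fixed at sigma_known; beta ~ N(m, diag(s^2)).
//                  Posterior is exactly normal.
//
// Uses R's RNG (RNGScope) so draws are reproducible via set.seed() on the R
// side.  Chains are run sequentially; chain c > 1 starts from an overdispersed
// draw from the prior.
//
// The conditional precision is constant for the "known" form and scales as
// 1/sigma2 for the "nig" form, so their Cholesky factors are computed once;
// only the "independent" form refactors per iteration, reusing one factor
// for both the mean solve and the multivariate draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec rnorm_vec(int k) {
  arma::vec z(k);
  for (int i = 0; i < k; ++i) z(i) = R::norm_rand();
  return z;
}

// forward substitution: solve R' w = b for upper-triangular R (in place)
static void solve_lower_t(const arma::mat& R, arma::vec& w) {
  const int k = R.n_rows;
  for (int i = 0; i < k; ++i) {
    double s = w(i);
    for (int j = 0; j < i; ++j) s -= R(j, i) * w(j);
    w(i) = s / R(i, i);
  }
}

// back substitution: solve R x = w for upper-triangular R (in place)
static void solve_upper(const arma::mat& R, arma::vec& x) {
  const int k = R.n_rows;
  for (int i = k - 1; i >= 0; --i) {
    double s = x(i);
    for (int j = i + 1; j < k; ++j) s -= R(i, j) * x(j);
    x(i) = s / R(i, i);
  }
}

// [[Rcpp::export]]
List gibbs_lm_cpp(const arma::vec& y, const arma::mat& X,
                  const arma::vec& prior_loc, const arma::vec& prior_scale,
                  double sigma_shape, double sigma_rate,
                  std::string form, double sigma_known,
                  int n_chains, int n_iter, int n_burnin) {
  const int n = X.n_rows, k = X.n_cols;
  const int n_keep = n_iter - n_burnin;
  if (n_keep <= 0) stop("n_burnin must be smaller than n_iter");

  const arma::mat XtX = X.t() * X;
  const arma::vec Xty = X.t() * y;
  const arma::vec P0diag = 1.0 / arma::square(prior_scale);
  const arma::vec P0m = P0diag % prior_loc;

  arma::mat beta_out(n_chains * n_keep, k);
  arma::vec sig2_out(n_chains * n_keep);
  IntegerVector chain_out(n_chains * n_keep);

  // constant pieces for the conjugate forms
  arma::mat Rfix;      // Cholesky (upper) of the fixed precision part
  arma::vec mufix;     // fixed conditional mean
  if (form == "known") {
    double s2 = sigma_known * sigma_known;
    arma::mat A = XtX / s2 + arma::diagmat(P0diag);
    if (!arma::chol(Rfix, A)) stop("Cholesky failure for the known-variance posterior");
    mufix = arma::solve(A, Xty / s2 + P0m);
  } else if (form == "nig") {
    arma::mat A = XtX + arma::diagmat(P0diag);
    if (!arma::chol(Rfix, A)) stop("Cholesky failure for the conjugate precision");
    mufix = arma::solve(A, Xty + P0m);
  }

  arma::mat A(k, k);
  arma::mat Rc(k, k);
  arma::vec b(k), mu(k), beta(k), resid(n);

  int row = 0;
  for (int c = 0; c < n_chains; ++c) {
    beta = prior_loc;
    if (c > 0) beta = prior_loc + prior_scale % rnorm_vec(k);
    double sig2 = (form == "known") ? sigma_known * sigma_known
                                    : sigma_rate / (sigma_shape + 1.0);

    for (int it = 0; it < n_iter; ++it) {
      // --- beta | sigma2 ---
      if (form == "known") {
        beta = mufix + arma::solve(arma::trimatu(Rfix), rnorm_vec(k));
      } else if (form == "nig") {
        beta = mufix + std::sqrt(sig2) *
          arma::solve(arma::trimatu(Rfix), rnorm_vec(k));
      } else {
        A = XtX / sig2;
        A.diag() += P0diag;
        if (!arma::chol(Rc, A))
          stop("Cholesky failure in Gibbs step (chain %d, iteration %d)",
               c + 1, it + 1);
        mu = Xty / sig2 + P0m;
        solve_lower_t(Rc, mu);          // R'w = b
        solve_upper(Rc, mu);            // R mu = w
        for (int i = 0; i < k; ++i) b(i) = R::norm_rand();
        solve_upper(Rc, b);             // draw: R z* = z
        beta = mu + b;
      }
      if (!beta.is_finite())
        stop("non-finite coefficient draw (chain %d, iteration %d)",
             c + 1, it + 1);

      // --- sigma2 | beta ---
      if (form != "known") {
        resid = y - X * beta;
        double rss = arma::dot(resid, resid);
        double shape_post, rate_post;
        if (form == "nig") {
          arma::vec d = beta - prior_loc;
          shape_post = sigma_shape + 0.5 * (n + k);
          rate_post  = sigma_rate + 0.5 * (rss + arma::dot(d % P0diag, d));
        } else {
          shape_post = sigma_shape + 0.5 * n;
          rate_post  = sigma_rate + 0.5 * rss;
        }
        sig2 = 1.0 / R::rgamma(shape_post, 1.0 / rate_post); // rate param.
        if (!std::isfinite(sig2) || sig2 <= 0.0)
          stop("non-finite variance draw (chain %d, iteration %d)",
               c + 1, it + 1);
      }

      if (it >= n_burnin) {
        beta_out.row(row) = beta.t();
        sig2_out(row) = sig2;
        chain_out[row] = c + 1;
        ++row;
      }
    }
  }

  return List::create(_["beta"] = beta_out,
                      _["sigma2"] = sig2_out,
                      _["chain"] = chain_out);
}
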