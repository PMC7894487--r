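// Gibbs sampler core for the Gaussian mixed model
//   y = X beta + u + e,  u ~ N(0, sigma2_p * A),  e ~ N(0, sigma2_e * I)
// run in the eigenbasis of A (A = Q diag(lambda) Q'): the wrapper rotates
// y and X by Q' once, so every full conditional here is diagonal or p x p.
//
// Block update: beta is drawn from its conditional with u integrated out
// (marginal covariance D = sigma2_p*lambda + sigma2_e, diagonal), then
// u | beta componentwise -- together an exact joint Gaussian draw of
// (beta, u), equivalent to the mixed-model-equations block.
//
// Priors: beta ~ N(0, beta_prior_var * I); each variance component
// scalar inverse-Wishart(V, nu) == inverse-gamma(nu/2, nu*V/2).
//
// lambda entries <= lambda_tol are treated as exact zeros (rank-deficient
// random-effect covariance, e.g. a group-incidence structure): those u
// components are fixed at 0 and excluded from the scale quadratic form.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double rinvgamma(double shape, double rate) {
  // X ~ Gamma(shape, rate) => 1/X ~ IG(shape, rate); R::rgamma takes scale
  double g = R::rgamma(shape, 1.0 / rate);
  return 1.0 / g;
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(const arma::vec& ytil, const arma::mat& Xtil,
                const arma::vec& lambda,
                const arma::vec& beta_init, double sigma2_p_init,
                double sigma2_e_init,
                double nu, double V, double beta_prior_var,
                int n_iter, int burn_in, int thin,
                bool fix_variances) {
  const int n = ytil.n_elem;
  const int p = Xtil.n_cols;
  const double lambda_tol = 1e-10;

  arma::uvec active = arma::find(lambda > lambda_tol);
  const int q_eff = active.n_elem;

  arma::vec beta = beta_init;
  arma::vec u(n, arma::fill::zeros);
  double sigma2_p = sigma2_p_init;
  double sigma2_e = sigma2_e_init;

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat draws(n_keep, p + 3);  // beta..., sigma2_p, sigma2_e, deviance
  arma::vec u_sum(n, arma::fill::zeros);

  const arma::mat prior_prec = arma::eye(p, p) / beta_prior_var;
  const double log2pi = std::log(2.0 * M_PI);

  int kept = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // marginal residual variances in the eigenbasis
    arma::vec d(n);
    for (int i = 0; i < n; ++i) {
      double l = (lambda(i) > lambda_tol) ? lambda(i) : 0.0;
      d(i) = sigma2_p * l + sigma2_e;
    }

    // beta | variances, y  (u integrated out)
    arma::mat Xw = Xtil.each_col() / d;           // D^{-1} X
    arma::mat P = Xtil.t() * Xw + prior_prec;     // p x p precision
    arma::vec b = Xw.t() * ytil;
    arma::mat R;
    if (!arma::chol(R, P)) {
      stop("singular normal equations for beta; consider rescaling predictors");
    }
    arma::vec m = arma::solve(arma::trimatu(R), arma::solve(arma::trimatl(R.t()), b));
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z(j) = R::norm_rand();
    beta = m + arma::solve(arma::trimatu(R), z);

    // u | beta, variances  (independent components in the eigenbasis)
    arma::vec r = ytil - Xtil * beta;
    double quad = 0.0;  // u' A^{-1} u  ==  sum u_i^2 / lambda_i over active
    u.zeros();
    for (int k = 0; k < q_eff; ++k) {
      int i = active(k);
      double vi = sigma2_p * lambda(i) * sigma2_e / d(i);
      double mi = vi * r(i) / sigma2_e;
      u(i) = mi + std::sqrt(vi) * R::norm_rand();
      quad += u(i) * u(i) / lambda(i);
    }

    // variance components | beta, u
    arma::vec resid = r - u;
    double sse = arma::dot(resid, resid);
    if (!fix_variances) {
      sigma2_p = rinvgamma((nu + q_eff) / 2.0, (nu * V + quad) / 2.0);
      sigma2_e = rinvgamma((nu + n) / 2.0, (nu * V + sse) / 2.0);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      double deviance = n * (log2pi + std::log(sigma2_e)) + sse / sigma2_e;
      for (int j = 0; j < p; ++j) draws(kept, j) = beta(j);
      draws(kept, p) = sigma2_p;
      draws(kept, p + 1) = sigma2_e;
      draws(kept, p + 2) = deviance;
      u_sum += u;
      ++kept;
    }
  }

  return List::create(_["draws"] = draws,
                      _["u_mean"] = u_sum / std::max(kept, 1),
                      _["n_kept"] = kept);
}
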