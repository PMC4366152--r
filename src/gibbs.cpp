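// Gibbs samplers for whole-genome regression with the three classical
// marker-effect priors: Bayesian LASSO (double-exponential), BayesA
// (scaled-t via per-marker inverse-chi-square variances) and BayesB
// (point mass at zero with probability pi + BayesA slab).
//
// Model: y = Z gamma + X beta + e,  e ~ N(0, sigma2e I).
// Fixed effects gamma carry a flat prior. Uses R's RNG so set.seed()
// in R makes runs exactly repeatable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Inverse-Gaussian sampler (Michael, Schucany & Haas 1976).
static double rinvgauss(double mu, double lambda) {
  double v = R::rnorm(0.0, 1.0);
  double w = v * v;
  double x = mu + (mu * mu * w) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * w + mu * mu * w * w);
  if (x <= 0.0) x = 1e-12;
  if (R::runif(0.0, 1.0) <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static double rscinvchisq(double df, double scale) {
  // scaled inverse chi-square: scale*df / chisq(df)
  return scale * df / R::rchisq(df);
}

// family: 0 = Bayesian LASSO, 1 = BayesA, 2 = BayesB
// [[Rcpp::export(name = ".gibbs_wgr")]]
List gibbs_wgr(const arma::mat& X, const arma::vec& y, const arma::mat& Z,
               int family, int niter, int burnin, int thin,
               double pi_zero, double nu_beta, double S_beta,
               double lambda2_init, bool sample_lambda,
               double lambda_shape, double lambda_rate,
               double sigma2e_init, bool sample_sigma2e,
               double nu_e, double S_e, bool keep_samples) {
  const int n = X.n_rows, p = X.n_cols, q = Z.n_cols;
  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));
  arma::vec ztz(q);
  for (int k = 0; k < q; ++k) ztz(k) = arma::dot(Z.col(k), Z.col(k));

  arma::vec beta(p, arma::fill::zeros);
  arma::vec gamma(q, arma::fill::zeros);
  arma::vec sig2b(p);          // per-marker prior variance (A/B) or tau^2 (BL)
  arma::uvec delta(p, arma::fill::ones); // BayesB inclusion indicators
  sig2b.fill(family == 0 ? 1.0 : S_beta);
  double sigma2e = sigma2e_init;
  double lambda2 = lambda2_init;

  arma::vec e = y - Z * gamma; // running residual (beta starts at 0)

  const int nkeep = (niter - burnin) / thin;
  arma::vec beta_mean(p, arma::fill::zeros);
  arma::vec gamma_mean(q, arma::fill::zeros);
  arma::vec incl_prob(p, arma::fill::zeros);
  arma::vec sigma2e_chain(nkeep, arma::fill::zeros);
  arma::vec mu_chain(nkeep, arma::fill::zeros);
  arma::mat beta_samp;
  if (keep_samples) beta_samp.zeros(nkeep, p);
  int kept = 0;

  for (int it = 0; it < niter; ++it) {
    // fixed effects, scalar Gibbs updates
    for (int k = 0; k < q; ++k) {
      if (ztz(k) <= 0) continue;
      double rhs = arma::dot(Z.col(k), e) + ztz(k) * gamma(k);
      double mean = rhs / ztz(k);
      double newg = R::rnorm(mean, std::sqrt(sigma2e / ztz(k)));
      e += Z.col(k) * (gamma(k) - newg);
      gamma(k) = newg;
    }

    // marker effects
    for (int j = 0; j < p; ++j) {
      if (xtx(j) <= 0) { beta(j) = 0.0; continue; }
      double rhs = arma::dot(X.col(j), e) + xtx(j) * beta(j);
      double priorvar = (family == 0) ? sigma2e * sig2b(j) : sig2b(j);

      if (family == 2) {
        // integrate beta out to sample the inclusion indicator
        double s2a = priorvar * xtx(j) / sigma2e + 1.0; // sig2b * a
        double logbf = 0.5 * priorvar * rhs * rhs /
          (sigma2e * (sigma2e + priorvar * xtx(j))) - 0.5 * std::log(s2a);
        double logodds = std::log(1.0 - pi_zero) - std::log(pi_zero) + logbf;
        double prob1 = (pi_zero <= 0.0) ? 1.0 :
          (pi_zero >= 1.0) ? 0.0 : 1.0 / (1.0 + std::exp(-logodds));
        delta(j) = (R::runif(0.0, 1.0) < prob1) ? 1u : 0u;
        if (delta(j) == 0u) {
          e += X.col(j) * beta(j);
          beta(j) = 0.0;
          sig2b(j) = rscinvchisq(nu_beta, S_beta); // refresh from prior
          continue;
        }
      }

      double c = xtx(j) + sigma2e / priorvar;
      double mean = rhs / c;
      double newb = R::rnorm(mean, std::sqrt(sigma2e / c));
      e += X.col(j) * (beta(j) - newb);
      beta(j) = newb;

      // per-marker variance updates
      if (family == 0) {
        double b2 = beta(j) * beta(j);
        if (b2 < 1e-14) b2 = 1e-14;
        double inv_tau2 = rinvgauss(std::sqrt(lambda2 * sigma2e / b2), lambda2);
        sig2b(j) = 1.0 / inv_tau2;
      } else {
        sig2b(j) = rscinvchisq(nu_beta + 1.0,
                               (S_beta * nu_beta + beta(j) * beta(j)) /
                                 (nu_beta + 1.0));
      }
    }

    if (family == 0 && sample_lambda) {
      double sum_tau2 = arma::accu(sig2b);
      lambda2 = R::rgamma(lambda_shape + p, 1.0 / (lambda_rate + sum_tau2 / 2.0));
    }

    if (sample_sigma2e) {
      double sse = arma::dot(e, e);
      if (family == 0) {
        // BL: beta | sigma2e scales with the residual variance
        double sb = 0.0;
        for (int j = 0; j < p; ++j) sb += beta(j) * beta(j) / sig2b(j);
        sigma2e = (sse + sb + S_e * nu_e) / R::rchisq(n + p + nu_e);
      } else {
        sigma2e = (sse + S_e * nu_e) / R::rchisq(n + nu_e);
      }
    }

    if (it >= burnin && (it - burnin) % thin == 0 && kept < nkeep) {
      beta_mean += beta;
      gamma_mean += gamma;
      for (int j = 0; j < p; ++j) if (beta(j) != 0.0) incl_prob(j) += 1.0;
      sigma2e_chain(kept) = sigma2e;
      mu_chain(kept) = q > 0 ? gamma(0) : 0.0;
      if (keep_samples) beta_samp.row(kept) = beta.t();
      ++kept;
    }
  }

  beta_mean /= std::max(kept, 1);
  gamma_mean /= std::max(kept, 1);
  incl_prob /= std::max(kept, 1);

  List out = List::create(
    Named("beta") = beta_mean, Named("gamma") = gamma_mean,
    Named("incl_prob") = incl_prob,
    Named("sigma2e_chain") = sigma2e_chain, Named("mu_chain") = mu_chain,
    Named("n_kept") = kept, Named("lambda2") = lambda2);
  if (keep_samples) out["beta_samples"] = beta_samp;
  return out;
}
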