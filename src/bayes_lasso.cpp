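// Gibbs sampler for Bayesian lasso logistic regression.
//
// Model: y_i ~ Bernoulli(logit^-1(alpha + x_i' beta)), flat prior on the
// intercept alpha, independent Laplace priors on the (standardized-scale)
// coefficients beta_j via the scale-mixture representation
//   beta_j | tau_j^2 ~ N(0, tau_j^2),  tau_j^2 ~ Exp(lambda^2 / 2),
// and a Gamma(a, b) hyperprior on lambda^2 so the global penalty is
// estimated from the data. The logistic likelihood is handled by
// Polya-Gamma data augmentation: omega_i ~ PG(1, eta_i) makes the
// conditional for (alpha, beta) Gaussian.
//
// All random numbers come from R's RNG so set.seed() gives bit-exact
// reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TRUNC = 0.64;  // Devroye crossover point for J*(1,z)

// alternating-series coefficients a_n(x) for the J*(1,z) density
static double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > TRUNC)
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
  return M_PI * np5 * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np5 * np5 / x);
}

// P(X <= t) for X ~ inverse-Gaussian(mu = 1/z, lambda = 1); valid at z = 0
static double pigauss(double t, double z) {
  double s = std::sqrt(1.0 / t);
  return R::pnorm(s * (t * z - 1.0), 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(-s * (t * z + 1.0), 0.0, 1.0, 1, 0);
}

// X ~ IG(1/z, 1) truncated to (0, TRUNC)
static double rtigauss(double z) {
  double X;
  if (z < 1.0 / TRUNC) {
    // mean above the truncation point: rejection via the chi-square trick
    for (;;) {
      double E1, E2;
      do {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      } while (E1 * E1 > 2.0 * E2 / TRUNC);
      X = TRUNC / ((1.0 + TRUNC * E1) * (1.0 + TRUNC * E1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * X)) return X;
    }
  }
  double mu = 1.0 / z;
  for (;;) {
    double Y = R::norm_rand();
    Y = Y * Y;
    double muY = mu * Y;
    X = mu + 0.5 * mu * muY - 0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
    if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    if (X < TRUNC) return X;
  }
}

// one draw from PG(1, z), Devroye's exact alternating-series method
static double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * fz)) * std::exp(-fz * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double X;
    if (R::unif_rand() < p / (p + q))
      X = TRUNC + R::exp_rand() / fz;   // exponential right tail
    else
      X = rtigauss(z);                  // truncated inverse-Gaussian body
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    for (int n = 1;; ++n) {
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return X / 4.0;
      } else {
        S += a_coef(n, X);
        if (Y > S) break;               // reject, propose again
      }
    }
  }
}

// inverse-Gaussian(mu, lambda) by the transform method
static double rigauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = mu * mu / x;  // numeric underflow guard
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".rpg_vec")]]
NumericVector rpg_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}

// [[Rcpp::export(name = ".bayes_lasso_gibbs")]]
List bayes_lasso_gibbs(const arma::mat& X, const arma::vec& y,
                       int n_draws, int n_burnin,
                       double lambda_a, double lambda_b) {
  const int n = X.n_rows, p = X.n_cols;
  arma::mat Z(n, p + 1);
  Z.col(0).ones();
  Z.cols(1, p) = X;
  const arma::vec Ztk = Z.t() * (y - 0.5);

  arma::vec beta(p + 1, arma::fill::zeros);
  arma::vec tau2(p, arma::fill::ones);
  double lambda2 = 1.0;

  const int keep = n_draws - n_burnin;
  arma::mat beta_out(keep, p);
  arma::vec alpha_out(keep), lambda2_out(keep);

  arma::vec omega(n), eta(n), e(p + 1);
  for (int it = 0; it < n_draws; ++it) {
    // 1. Polya-Gamma latents
    eta = Z * beta;
    for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);

    // 2. Gaussian conditional for (alpha, beta)
    arma::mat P = Z.t() * (Z.each_col() % omega);
    for (int j = 0; j < p; ++j) P(j + 1, j + 1) += 1.0 / tau2[j];
    arma::mat L = arma::chol(P, "lower");
    arma::vec w = arma::solve(arma::trimatl(L), Ztk);
    arma::vec m = arma::solve(arma::trimatu(L.t()), w);
    for (int j = 0; j <= p; ++j) e[j] = R::norm_rand();
    beta = m + arma::solve(arma::trimatu(L.t()), e);

    // 3. local scales: 1/tau_j^2 ~ IG(sqrt(lambda^2)/|beta_j|, lambda^2)
    double sl = std::sqrt(lambda2);
    for (int j = 0; j < p; ++j) {
      double bj = std::max(std::fabs(beta[j + 1]), 1e-10);
      double itau2 = rigauss(std::min(sl / bj, 1e8), lambda2);
      tau2[j] = 1.0 / std::max(itau2, 1e-12);
    }

    // 4. global penalty: lambda^2 | tau ~ Gamma(a + p, b + sum(tau2)/2)
    lambda2 = R::rgamma(lambda_a + p, 1.0 / (lambda_b + arma::accu(tau2) / 2.0));

    if (it >= n_burnin) {
      int k = it - n_burnin;
      alpha_out[k] = beta[0];
      beta_out.row(k) = beta.subvec(1, p).t();
      lambda2_out[k] = lambda2;
    }
  }
  return List::create(_["intercept"] = alpha_out, _["beta"] = beta_out,
                      _["lambda2"] = lambda2_out);
}
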