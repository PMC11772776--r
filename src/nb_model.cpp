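#include <Rcpp.h>
using namespace Rcpp;

// Negative binomial regression of raw counts r on DNA copy number, with an
// identity link on the tissue-resolved linear predictor
//
//   mu_j = beta1[t(j)] * c_j * p_j + beta2 * d_j * p_j + beta3[t(j)] * (1 - p_j)
//   r_j ~ NB(mean = s_j * m * mu_j, shape)
//
// c = euploid equivalents (linear copy ratio), d = c - 1 (euploid deviation),
// p = tumor purity (1 for cell lines, where the beta3 term is dropped),
// sm_j = s_j * m folds the per-sample size factor and the gene mean together.
//
// Parameters are sampled on an unconstrained scale:
//   theta = (log beta1[1..T], beta2, [log beta3[1..T] if tumor], log shape)
// matching the priors log beta1, log beta3 ~ N(0,1); beta2 ~ N(0, b2_sd);
// shape ~ Gamma(0.01, rate 0.01) with the log-scale Jacobian applied.
// Draws implying mu <= 0 for any retained sample have zero posterior mass
// (the identity link does not itself keep the NB mean positive).

static double log_posterior(const NumericVector &theta,
                            const IntegerVector &r,
                            const NumericVector &c,
                            const NumericVector &d,
                            const NumericVector &p,
                            const NumericVector &sm,
                            const IntegerVector &tissue,
                            const int T,
                            const bool tumor,
                            const double b2_sd) {
  const int n = r.size();
  const int P = theta.size();
  const double lshape = theta[P - 1];
  const double shape = std::exp(lshape);
  if (!R_finite(shape) || shape <= 0.0) return R_NegInf;

  double lp = 0.0;
  for (int t = 0; t < T; ++t) lp += R::dnorm(theta[t], 0.0, 1.0, 1);
  lp += R::dnorm(theta[T], 0.0, b2_sd, 1);
  if (tumor)
    for (int t = 0; t < T; ++t) lp += R::dnorm(theta[T + 1 + t], 0.0, 1.0, 1);
  lp += R::dgamma(shape, 0.01, 1.0 / 0.01, 1) + lshape;

  const double b2 = theta[T];
  for (int j = 0; j < n; ++j) {
    const int t = tissue[j];
    double mu = std::exp(theta[t]) * c[j] * p[j] + b2 * d[j] * p[j];
    if (tumor) mu += std::exp(theta[T + 1 + t]) * (1.0 - p[j]);
    if (!(mu > 0.0)) return R_NegInf;
    lp += R::dnbinom_mu((double) r[j], shape, sm[j] * mu, 1);
  }
  return lp;
}

// [[Rcpp::export(name = ".nb_model_loglik_cpp")]]
double nb_model_loglik_cpp(IntegerVector r, NumericVector c, NumericVector d,
                           NumericVector p, NumericVector sm,
                           IntegerVector tissue, int n_tissues, bool tumor,
                           NumericVector beta1, double beta2,
                           NumericVector beta3, double shape) {
  const int n = r.size();
  double ll = 0.0;
  for (int j = 0; j < n; ++j) {
    const int t = tissue[j];
    double mu = beta1[t] * c[j] * p[j] + beta2 * d[j] * p[j];
    if (tumor) mu += beta3[t] * (1.0 - p[j]);
    if (!(mu > 0.0)) return R_NegInf;
    ll += R::dnbinom_mu((double) r[j], shape, sm[j] * mu, 1);
  }
  return ll;
}

// [[Rcpp::export(name = ".nb_log_posterior_cpp")]]
double nb_log_posterior_cpp(NumericVector theta, IntegerVector r,
                            NumericVector c, NumericVector d, NumericVector p,
                            NumericVector sm, IntegerVector tissue,
                            int n_tissues, bool tumor, double b2_sd) {
  return log_posterior(theta, r, c, d, p, sm, tissue, n_tissues, tumor, b2_sd);
}

// Lower-triangular Cholesky factor of a small SPD matrix (row-major,
// dimension P); jitters the diagonal if needed.
static void cholesky(std::vector<double> &a, int P) {
  for (int i = 0; i < P; ++i) a[i * P + i] += 1e-10;
  for (int i = 0; i < P; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = a[i * P + j];
      for (int k = 0; k < j; ++k) s -= a[i * P + k] * a[j * P + k];
      if (i == j) {
        a[i * P + i] = std::sqrt(std::max(s, 1e-12));
      } else {
        a[i * P + j] = s / a[j * P + j];
      }
    }
    for (int j = i + 1; j < P; ++j) a[i * P + j] = 0.0;
  }
}

// One MCMC chain.  Warmup runs component-wise adaptive random-walk
// Metropolis (Robbins-Monro toward 0.44 acceptance); the second half of
// warmup also accumulates an empirical posterior covariance, whose
// Cholesky factor then drives a short joint-proposal tuning segment
// (global scale adapted toward 0.23 acceptance, Haario-style) before
// sampling with all adaptation frozen.  The joint proposal handles the
// beta1/beta2 correlation that compensated genes induce.  Uses R's RNG,
// so runs are reproducible under set.seed().
// [[Rcpp::export(name = ".nb_mh_chain_cpp")]]
NumericMatrix nb_mh_chain_cpp(IntegerVector r, NumericVector c,
                              NumericVector d, NumericVector p,
                              NumericVector sm, IntegerVector tissue,
                              int n_tissues, bool tumor, double b2_sd,
                              NumericVector init, int warmup, int iter) {
  const int P = init.size();
  NumericVector theta = clone(init);
  NumericVector lsd(P, -1.5);
  double lp = log_posterior(theta, r, c, d, p, sm, tissue, n_tissues, tumor,
                            b2_sd);
  if (!R_finite(lp))
    stop("initial parameter values have zero posterior density");

  // phase 1: component-wise adaptation, accumulating covariance moments
  std::vector<double> mean_acc(P, 0.0), cov_acc(P * P, 0.0);
  int n_acc = 0;
  for (int it = 0; it < warmup; ++it) {
    for (int k = 0; k < P; ++k) {
      const double old = theta[k];
      theta[k] = old + std::exp(lsd[k]) * R::norm_rand();
      const double lp_new = log_posterior(theta, r, c, d, p, sm, tissue,
                                          n_tissues, tumor, b2_sd);
      const bool accept = R_finite(lp_new) &&
        (std::log(R::unif_rand()) < lp_new - lp);
      if (accept) lp = lp_new; else theta[k] = old;
      const double eta = std::min(0.25, 2.0 / std::sqrt((double) (it + 1)));
      lsd[k] += eta * ((accept ? 1.0 : 0.0) - 0.44);
      if (lsd[k] < -10.0) lsd[k] = -10.0;
      if (lsd[k] > 4.0) lsd[k] = 4.0;
    }
    if (it >= warmup / 2) {
      for (int a = 0; a < P; ++a) {
        mean_acc[a] += theta[a];
        for (int b = 0; b <= a; ++b) cov_acc[a * P + b] += theta[a] * theta[b];
      }
      ++n_acc;
    }
  }

  // empirical covariance -> Cholesky proposal factor
  std::vector<double> L(P * P, 0.0);
  bool have_cov = n_acc >= 10;
  if (have_cov) {
    for (int a = 0; a < P; ++a) {
      const double ma = mean_acc[a] / n_acc;
      for (int b = 0; b <= a; ++b) {
        const double mb = mean_acc[b] / n_acc;
        double cv = cov_acc[a * P + b] / n_acc - ma * mb;
        L[a * P + b] = cv;
        L[b * P + a] = cv;
      }
    }
    cholesky(L, P);
  } else {
    for (int a = 0; a < P; ++a) L[a * P + a] = std::exp(lsd[a]);
  }

  // phase 2: tune the global scale of the joint proposal, then freeze
  const double base_scale = 2.38 / std::sqrt((double) P);
  double lscale = std::log(base_scale);
  const int tune = std::max(warmup / 2, 50);
  std::vector<double> z(P), prop(P);
  NumericMatrix out(iter, P);
  const int total = tune + iter;
  for (int it = 0; it < total; ++it) {
    for (int k = 0; k < P; ++k) z[k] = R::norm_rand();
    const double s = std::exp(lscale);
    for (int a = 0; a < P; ++a) {
      double step = 0.0;
      for (int b = 0; b <= a; ++b) step += L[a * P + b] * z[b];
      prop[a] = theta[a] + s * step;
    }
    NumericVector cand(prop.begin(), prop.end());
    const double lp_new = log_posterior(cand, r, c, d, p, sm, tissue,
                                        n_tissues, tumor, b2_sd);
    const bool accept = R_finite(lp_new) &&
      (std::log(R::unif_rand()) < lp_new - lp);
    if (accept) {
      lp = lp_new;
      std::copy(prop.begin(), prop.end(), theta.begin());
    }
    if (it < tune) {
      const double eta = std::min(0.25, 2.0 / std::sqrt((double) (it + 1)));
      lscale += eta * ((accept ? 1.0 : 0.0) - 0.23);
      lscale = std::min(std::max(lscale, std::log(base_scale) - 4.0),
                        std::log(base_scale) + 2.0);
    } else {
      out(it - tune, _) = theta;
    }
  }
  return out;
}
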