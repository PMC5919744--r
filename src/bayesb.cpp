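#include <Rcpp.h>
using namespace Rcpp;

// BayesB Gibbs sampler on centered marker covariates.
// Model: y = mu + W beta + e
//   beta_j = 0 with prob 1 - delta_j; beta_j | delta_j = 1 ~ N(0, s2_j)
//   s2_j ~ scaled-inv-chisq(df_beta, S_beta)
//   delta_j ~ Bernoulli(pi), pi ~ Beta(p0 * pi0, p0 * (1 - pi0))
//   sigma2_e ~ scaled-inv-chisq(df_e, S_e)
// Uses R's RNG, so results are reproducible under set.seed().

static double rinvchisq(double df, double scale) {
  return scale * df / R::rchisq(df);
}

// [[Rcpp::export]]
List bayesb_gibbs(NumericVector y, NumericMatrix W, int iters,
                  int burnin, int thin, double df_beta, double S_beta,
                  double pi0, double p0, double df_e, double S_e) {
  const int n = W.nrow(), m = W.ncol();
  std::vector<double> xx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    xx[j] = s;
  }
  std::vector<double> beta(m, 0.0), s2(m);
  std::vector<int> delta(m, 0);
  for (int j = 0; j < m; ++j) s2[j] = rinvchisq(df_beta, S_beta / df_beta);
  double mu = mean(y);
  double pi = pi0;
  double sigma2_e = S_e / (df_e + 2.0);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> beta_sum(m, 0.0), incl_sum(m, 0.0);
  double mu_sum = 0.0, pi_sum = 0.0, s2e_sum = 0.0;
  int n_saved = 0;

  for (int it = 1; it <= iters; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i] + mu;
    ebar /= n;
    double mu_new = ebar + R::norm_rand() * std::sqrt(sigma2_e / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    int n_in = 0;
    for (int j = 0; j < m; ++j) {
      if (xx[j] <= 0.0) { beta[j] = 0.0; delta[j] = 0; continue; }
      // restore residual without marker j
      if (beta[j] != 0.0)
        for (int i = 0; i < n; ++i) e[i] += W(i, j) * beta[j];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += W(i, j) * e[i];
      // log Bayes factor for inclusion with beta_j integrated out
      double v = sigma2_e + xx[j] * s2[j];
      double logbf = 0.5 * std::log(sigma2_e / v) +
        0.5 * rhs * rhs * s2[j] / (sigma2_e * v);
      double logodds = std::log(pi / (1.0 - pi)) + logbf;
      double prob = 1.0 / (1.0 + std::exp(-logodds));
      if (R::unif_rand() < prob) {
        delta[j] = 1;
        ++n_in;
        double vpost = 1.0 / (xx[j] / sigma2_e + 1.0 / s2[j]);
        double mpost = vpost * rhs / sigma2_e;
        beta[j] = mpost + R::norm_rand() * std::sqrt(vpost);
        for (int i = 0; i < n; ++i) e[i] -= W(i, j) * beta[j];
      } else {
        delta[j] = 0;
        beta[j] = 0.0;
      }
      // marker variance: posterior when included, prior draw otherwise
      double dfp = df_beta + delta[j];
      double Sp = S_beta + beta[j] * beta[j];
      s2[j] = rinvchisq(dfp, Sp / dfp);
      if (!R_finite(s2[j]) || s2[j] <= 0.0)
        stop("non-finite marker variance at iteration %d", it);
    }
    // mixing proportion
    pi = R::rbeta(p0 * pi0 + n_in, p0 * (1.0 - pi0) + (m - n_in));
    pi = std::min(std::max(pi, 1e-6), 1.0 - 1e-6);
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2_e = (sse + S_e) / R::rchisq(n + df_e);
    if (!R_finite(sigma2_e) || sigma2_e <= 0.0)
      stop("non-finite residual variance at iteration %d", it);

    if (it > burnin && ((it - burnin) % thin == 0)) {
      ++n_saved;
      for (int j = 0; j < m; ++j) {
        beta_sum[j] += beta[j];
        incl_sum[j] += delta[j];
      }
      mu_sum += mu;
      pi_sum += pi;
      s2e_sum += sigma2_e;
    }
  }
  if (n_saved == 0) stop("no post-burnin samples saved");
  NumericVector bmean(m), imean(m);
  for (int j = 0; j < m; ++j) {
    bmean[j] = beta_sum[j] / n_saved;
    imean[j] = incl_sum[j] / n_saved;
  }
  return List::create(_["beta"] = bmean, _["inclusion"] = imean,
                      _["mu"] = mu_sum / n_saved,
                      _["pi"] = pi_sum / n_saved,
                      _["sigma2_e"] = s2e_sum / n_saved,
                      _["n_saved"] = n_saved);
}
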