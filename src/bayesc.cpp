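#include <Rcpp.h>
using namespace Rcpp;

// BayesC Gibbs sampler.
//
// Model: y = 1*mu + sum_j w_j d_j s_j + e,
//   d_j ~ Bernoulli(pi), s_j | d_j=1 ~ N(0, s2s), e ~ N(0, s2e I),
//   s2s and s2e ~ scaled-inverse-chi^2(nu, S).
// Full conditionals are standard: the inclusion indicator is sampled from
// its conditional odds (marginalized over s_j), then the effect from its
// conditional normal; variances from scaled-inverse-chi^2.
// Uses R's RNG, so results are reproducible via set.seed() in R.

static double rinvchisq(double nu, double scale) {
  // scaled-inverse-chi^2(nu, scale) draw
  return nu * scale / R::rchisq(nu);
}

// [[Rcpp::export(name = ".bayesc_gibbs")]]
List bayesc_gibbs(NumericVector y, NumericMatrix W,
                  double pi_prior, int n_iter, int burn_in, int thin,
                  double nu_s, double scale_s, double nu_e, double scale_e) {
  const int n = y.size();
  const int m = W.ncol();
  if (W.nrow() != n) stop("dim mismatch between y and W");

  std::vector<double> wtw(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double* wj = &W(0, j);
    for (int i = 0; i < n; ++i) s += wj[i] * wj[i];
    wtw[j] = s;
  }

  std::vector<double> s(m, 0.0);   // effects
  std::vector<int> d(m, 0);        // indicators
  double mu = mean(y);
  double s2s = scale_s * nu_s / std::max(nu_s - 2.0, 0.5);
  double s2e = scale_e * nu_e / std::max(nu_e - 2.0, 0.5);

  std::vector<double> e(n);        // residual y - mu - W d s
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> d_sum(m, 0.0), eff_sum(m, 0.0);
  double s2s_sum = 0.0, s2e_sum = 0.0, mu_sum = 0.0;
  int n_kept = 0;
  const double log_prior_odds = std::log(pi_prior) - std::log1p(-pi_prior);

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double esum = 0.0;
    for (int i = 0; i < n; ++i) esum += e[i] + mu;
    double mu_new = R::rnorm(esum / n, std::sqrt(s2e / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    double ssq_eff = 0.0;
    int m_in = 0;
    const double lambda = s2e / s2s;
    for (int j = 0; j < m; ++j) {
      const double* wj = &W(0, j);
      if (wtw[j] <= 0.0) { d[j] = 0; s[j] = 0.0; continue; }
      // rhs = w_j' (residual with marker j removed)
      double wte = 0.0;
      for (int i = 0; i < n; ++i) wte += wj[i] * e[i];
      const double rhs = wte + wtw[j] * s[j] * d[j];
      const double c = wtw[j] + lambda;
      // log marginal-likelihood ratio for d_j = 1 vs 0
      const double log_lr = 0.5 * (std::log(lambda) - std::log(c)) +
                            rhs * rhs / (2.0 * s2e * c);
      const double log_odds = log_prior_odds + log_lr;
      const double p1 = 1.0 / (1.0 + std::exp(-log_odds));
      const int d_new = (R::unif_rand() < p1) ? 1 : 0;
      double s_new = 0.0;
      if (d_new == 1) {
        s_new = R::rnorm(rhs / c, std::sqrt(s2e / c));
        ssq_eff += s_new * s_new;
        ++m_in;
      }
      // residual update for the change in the fitted value of marker j
      const double diff = s[j] * d[j] - s_new * d_new;
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] += wj[i] * diff;
      s[j] = s_new;
      d[j] = d_new;
    }

    // effect variance (common to all included markers)
    s2s = rinvchisq(nu_s + m_in, (ssq_eff + nu_s * scale_s) / (nu_s + m_in));
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = rinvchisq(nu_e + n, (sse + nu_e * scale_e) / (nu_e + n));

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      for (int j = 0; j < m; ++j) {
        d_sum[j] += d[j];
        eff_sum[j] += s[j] * d[j];
      }
      s2s_sum += s2s;
      s2e_sum += s2e;
      mu_sum += mu;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector d_hat(m), eff(m);
  for (int j = 0; j < m; ++j) {
    d_hat[j] = d_sum[j] / n_kept;
    eff[j] = eff_sum[j] / n_kept;
  }
  return List::create(_["d_hat"] = d_hat,
                      _["effect"] = eff,
                      _["n_samples"] = n_kept,
                      _["mu"] = mu_sum / n_kept,
                      _["s2_effect"] = s2s_sum / n_kept,
                      _["s2_residual"] = s2e_sum / n_kept);
}
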