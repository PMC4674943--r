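#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the two-component mixture regression
//   y_i = mu + sum_j x_ij beta_j + e_i,   e_i ~ N(0, sigma_e^2 / w_i)
//   beta_j ~ N(0, sigma_g0^2) w.p. pi0,  N(0, sigma_g1^2) w.p. pi1
// Indicators and effects are drawn from their conjugate full conditionals.
// sigma_e^2 uses a conjugate scaled-inverse-chi-square draw (Jeffreys
// prior); sigma_g1^2 uses a scale-invariant conditional with one
// pseudo-observation at a floor 100x the null-component variance (keeps the
// draw proper when the large component is empty), capped at the response
// variance, followed by one random-walk Metropolis-Hastings refinement of
// size mh_step on the log scale targeting the same conditional. sigma_g0^2
// stays fixed. Uses R's RNG so set.seed() makes the chain reproducible.
//
// X must already be column-centred; mu absorbs the centring constant.
// [[Rcpp::export]]
List cpp_bvs_mcmc(NumericMatrix X, NumericVector y, NumericVector w,
                  double pi1, int n_iter, int burnin, double mh_step,
                  double sigma2_g0, double sigma2_g1_init, double sigma2_e_init,
                  int dev_thin) {
  int n = X.nrow(), p = X.ncol();
  double pi0 = 1.0 - pi1;
  double ybar = 0.0, cap_var = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  for (int i = 0; i < n; ++i) cap_var += (y[i] - ybar) * (y[i] - ybar);
  cap_var /= (n - 1);
  std::vector<double> beta(p, 0.0);
  std::vector<int> delta(p, 0);
  double mu = 0.0, s2e = sigma2_e_init, s2g1 = sigma2_g1_init;

  // precompute weighted cross-products x_j' W x_j and sum of weights
  std::vector<double> xtwx(p);
  double sw = 0.0;
  for (int i = 0; i < n; ++i) sw += w[i];
  for (int j = 0; j < p; ++j) {
    const double *xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
    xtwx[j] = s;
  }

  std::vector<double> r(n); // residual y - mu - X beta
  for (int i = 0; i < n; ++i) r[i] = y[i];
  // weighted design copy so the per-SNP right-hand side is one dot product;
  // skipped when all weights are equal (then rhs = w0 * x_j' r)
  bool unit_w = true;
  for (int i = 1; i < n; ++i) if (w[i] != w[0]) { unit_w = false; break; }
  std::vector<double> WX;
  if (!unit_w) {
    WX.resize((size_t)n * p);
    for (int j = 0; j < p; ++j) {
      const double *xj = &X(0, j);
      double *wxj = &WX[(size_t)j * n];
      for (int i = 0; i < n; ++i) wxj[i] = w[i] * xj[i];
    }
  }
  const int inc1 = 1;

  std::vector<double> sum_delta(p, 0.0), sum_beta(p, 0.0);
  double sum_mu = 0.0, sum_s2e = 0.0, sum_s2g1 = 0.0, sum_m1 = 0.0;
  int n_keep = 0, acc_e = 0, acc_g = 0;
  int n_dev = n_iter / dev_thin;
  NumericVector dev_trace(n_dev);
  IntegerVector dev_iter(n_dev);
  int dev_k = 0;

  double log_pi1 = std::log(pi1), log_pi0 = std::log(pi0 > 0 ? pi0 : 1e-300);

  for (int it = 0; it < n_iter; ++it) {
    // --- SNP indicators and effects ---
    for (int j = 0; j < p; ++j) {
      const double *xj = &X(0, j);
      double rhs = xtwx[j] * beta[j] +
        (unit_w ? w[0] * F77_CALL(ddot)(&n, xj, &inc1, r.data(), &inc1)
                : F77_CALL(ddot)(&n, &WX[(size_t)j * n], &inc1, r.data(), &inc1));
      // marginal (beta integrated out) log-likelihood ratio of the two
      // components: 1 + xtwx*sigma2/s2e = sigma2*den/s2e, so the two log1p
      // terms collapse into one log of a ratio
      double den0 = xtwx[j] + s2e / sigma2_g0;
      double den1 = xtwx[j] + s2e / s2g1;
      double lr = -0.5 * std::log(s2g1 * den1 / (sigma2_g0 * den0)) +
        0.5 * rhs * rhs / s2e * (1.0 / den1 - 1.0 / den0);
      double lo = lr + log_pi1 - log_pi0;
      double p1;
      if (pi1 >= 1.0 || lo > 50.0) p1 = 1.0;
      else if (lo < -50.0) p1 = 0.0;
      else { double o = std::exp(lo); p1 = o / (1.0 + o); }
      int dj = (R::unif_rand() < p1) ? 1 : 0;
      double den = dj ? den1 : den0;
      double bnew = rhs / den + R::norm_rand() * std::sqrt(s2e / den);
      double ndb = beta[j] - bnew;
      if (ndb != 0.0) F77_CALL(daxpy)(&n, &ndb, xj, &inc1, r.data(), &inc1);
      beta[j] = bnew; delta[j] = dj;
    }
    // --- overall mean (flat prior) ---
    double rhs_mu = 0.0;
    for (int i = 0; i < n; ++i) rhs_mu += w[i] * (r[i] + mu);
    double mu_new = rhs_mu / sw + R::norm_rand() * std::sqrt(s2e / sw);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) r[i] -= dmu;
    mu = mu_new;
    // --- residual variance: conjugate scaled-inverse-chi-square draw ---
    double ssrw = 0.0;
    for (int i = 0; i < n; ++i) ssrw += w[i] * r[i] * r[i];
    s2e = ssrw / R::rchisq((double)n);
    ++acc_e;
    // --- large-component variance: conjugate draw + one MH refinement ---
    // scale-invariant (Jeffreys) conditional so sigma_g1^2 tracks the
    // effects actually in the large component; floored above the null
    // component's scale so the two components stay distinguishable
    {
      const double floor_g1 = 100.0 * sigma2_g0;
      const double cap_g1 = cap_var; // no single effect beyond the trait variance
      int m1 = 0; double ssb = 0.0;
      for (int j = 0; j < p; ++j) if (delta[j]) { ++m1; ssb += beta[j] * beta[j]; }
      // one pseudo-observation at the floor scale keeps the draw proper when
      // the large component is momentarily empty and tames the chi-square tail
      s2g1 = (ssb + floor_g1) / R::rchisq((double)(m1 + 1));
      if (mh_step > 0) {
        // log-scale random walk on the same conditional (kept invariant)
        double prop = s2g1 * std::exp(mh_step * R::norm_rand());
        double lt_cur = -0.5 * (m1 + 1) * std::log(s2g1) -
          0.5 * (ssb + floor_g1) / s2g1;
        double lt_prop = -0.5 * (m1 + 1) * std::log(prop) -
          0.5 * (ssb + floor_g1) / prop;
        if (std::log(R::unif_rand()) < lt_prop - lt_cur) { s2g1 = prop; ++acc_g; }
      }
      if (s2g1 < floor_g1) s2g1 = floor_g1;
      if (s2g1 > cap_g1) s2g1 = cap_g1;
      if (it >= burnin) sum_m1 += m1;
    }
    // --- deviance trace ---
    if ((it + 1) % dev_thin == 0 && dev_k < n_dev) {
      double dev = n * std::log(2.0 * M_PI * s2e) + ssrw / s2e;
      for (int i = 0; i < n; ++i) dev -= std::log(w[i]);
      dev_trace[dev_k] = dev;
      dev_iter[dev_k] = it + 1;
      ++dev_k;
    }
    // --- accumulate posterior summaries ---
    if (it >= burnin) {
      ++n_keep;
      for (int j = 0; j < p; ++j) { sum_delta[j] += delta[j]; sum_beta[j] += beta[j]; }
      sum_mu += mu; sum_s2e += s2e; sum_s2g1 += s2g1;
    }
  }

  NumericVector pip(p), beta_bar(p);
  for (int j = 0; j < p; ++j) { pip[j] = sum_delta[j] / n_keep; beta_bar[j] = sum_beta[j] / n_keep; }
  return List::create(
    _["pip"] = pip, _["beta_bar"] = beta_bar,
    _["mu"] = sum_mu / n_keep, _["sigma2_e"] = sum_s2e / n_keep,
    _["sigma2_g1"] = sum_s2g1 / n_keep,
    _["mean_n_large"] = sum_m1 / n_keep,
    _["accept_e"] = (double)acc_e / n_iter, _["accept_g1"] = (double)acc_g / n_iter,
    _["deviance"] = dev_trace[Rcpp::Range(0, dev_k - 1)],
    _["deviance_iter"] = dev_iter[Rcpp::Range(0, dev_k - 1)],
    _["n_kept"] = n_keep);
}
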