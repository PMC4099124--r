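#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the spike-and-slab mixture regression
//   y_i = mu + sum_j x_ij beta_j + e_i,  e_i ~ N(0, sigma2_e)
//   beta_j ~ pi N(0, tau * sigma2_beta) + (1 - pi) N(0, sigma2_beta)
// with pi ~ Uniform(0,1), sigma2_beta ~ ScaledInvChisq(v_beta, S2_beta),
// sigma2_e ~ ScaledInvChisq(v_e, S2_e) and a flat prior on mu.
//
// The mixture weight pi sits on the spike (near-zero) component when
// pi_on_spike is true, so a large posterior pi means few SNPs carry effects.
// (delta_j, beta_j) are updated jointly: delta_j from its two-point
// conditional with beta_j integrated out, then beta_j from its normal
// conditional given delta_j. The residual vector is updated incrementally
// and refreshed from scratch every refresh_every sweeps; the largest
// deviation seen at refresh points is returned (resid_drift).
//
// update_pi / fix_var_beta / fix_var_e allow conditioning on known values
// for conjugate-oracle validation. Uses R's RNG (set.seed-reproducible).
// [[Rcpp::export]]
List cpp_gibbs_mixture(const NumericVector& y, const NumericMatrix& X,
                       double tau, double v_beta, double S2_beta,
                       double v_e, double S2_e,
                       int n_iter, int burn_in, int thin,
                       bool update_pi, double pi_init, bool pi_on_spike,
                       bool fix_var_beta, double sigma2_beta_init,
                       bool fix_var_e, double sigma2_e_init,
                       int refresh_every) {
  const int n = y.size();
  const int m = X.ncol();

  // sufficient statistics per SNP; raw column pointers keep the hot
  // loops vectorisable
  const double* Xp = &X(0, 0);
  std::vector<double> xx(m);
  for (int j = 0; j < m; ++j) {
    const double* xj = Xp + (size_t) j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xx[j] = s;
  }
  int m_used = 0;
  for (int j = 0; j < m; ++j) if (xx[j] > 0.0) ++m_used;

  // state
  double mu = Rcpp::mean(y);
  std::vector<double> beta(m, 0.0);
  std::vector<int> delta(m, 0);           // 1 = slab
  double pi = pi_init;
  double s2b = sigma2_beta_init > 0.0 ? sigma2_beta_init
                                      : v_beta * S2_beta / (v_beta - 2.0);
  double s2e = sigma2_e_init > 0.0 ? sigma2_e_init
                                   : v_e * S2_e / (v_e - 2.0);
  std::vector<double> ev(n);
  double* e = ev.data();
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  // accumulators
  std::vector<double> beta_sum(m, 0.0), incl_sum(m, 0.0);
  double mu_sum = 0, pi_sum = 0, s2b_sum = 0, s2e_sum = 0;
  int n_kept = 0;
  int n_chain = (n_iter - burn_in + thin - 1) / thin;
  NumericVector pi_chain(n_chain), s2b_chain(n_chain), s2e_chain(n_chain),
      mu_chain(n_chain);
  // full effect chains are kept only for very small m (oracle checks)
  const bool keep_beta_chain = m <= 8;
  NumericMatrix beta_chain(keep_beta_chain ? n_chain : 0,
                           keep_beta_chain ? m : 0);
  int chain_at = 0;
  double resid_drift = 0.0;

  for (int it = 1; it <= n_iter; ++it) {
    // mu | rest (flat prior)
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + norm_rand() * std::sqrt(s2e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // (delta_j, beta_j) jointly, systematic scan
    const double v_spike = tau * s2b, v_slab = s2b;
    const double w_spike = pi_on_spike ? pi : 1.0 - pi;
    const double lw0 = w_spike > 0.0 ? std::log(w_spike) : R_NegInf;
    const double lw1 = w_spike < 1.0 ? std::log(1.0 - w_spike) : R_NegInf;
    double sum_b2t = 0.0;   // sum beta_j^2 / t_j with t_j = tau (spike) or 1
    int n_slab = 0;
    for (int j = 0; j < m; ++j) {
      if (xx[j] <= 0.0) continue;        // monomorphic column: effect stays 0
      const double* xj = Xp + (size_t) j * n;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      rhs += xx[j] * beta[j];
      // marginal of rhs given delta: N(0, xx^2 v + xx s2e)
      double var0 = xx[j] * (xx[j] * v_spike + s2e);
      double var1 = xx[j] * (xx[j] * v_slab + s2e);
      double l0 = lw0 - 0.5 * std::log(var0) - 0.5 * rhs * rhs / var0;
      double l1 = lw1 - 0.5 * std::log(var1) - 0.5 * rhs * rhs / var1;
      double lmax = l0 > l1 ? l0 : l1;
      double p1 = std::exp(l1 - lmax) /
                  (std::exp(l0 - lmax) + std::exp(l1 - lmax));
      int d = unif_rand() < p1 ? 1 : 0;
      double vc = d ? v_slab : v_spike;
      double prec = xx[j] / s2e + 1.0 / vc;
      double bmean = (rhs / s2e) / prec;
      double bnew = bmean + norm_rand() / std::sqrt(prec);
      double db = bnew - beta[j];
      if (db != 0.0) for (int i = 0; i < n; ++i) e[i] -= xj[i] * db;
      beta[j] = bnew;
      delta[j] = d;
      n_slab += d;
      sum_b2t += bnew * bnew / (d ? 1.0 : tau);
    }

    // pi | delta  (uniform prior -> Beta conjugacy)
    if (update_pi) {
      int n_spike = m_used - n_slab;
      double a = pi_on_spike ? 1.0 + n_spike : 1.0 + n_slab;
      double b = pi_on_spike ? 1.0 + n_slab : 1.0 + n_spike;
      pi = R::rbeta(a, b);
    }

    // sigma2_beta | beta, delta  (scaled-inv-chisq conditional)
    if (!fix_var_beta) {
      double df = v_beta + m_used;
      s2b = (v_beta * S2_beta + sum_b2t) / R::rchisq(df);
    }

    // sigma2_e | e
    if (!fix_var_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      double df = v_e + n;
      s2e = (v_e * S2_e + sse) / R::rchisq(df);
    }

    // periodic residual refresh; track incremental drift
    if (refresh_every > 0 && it % refresh_every == 0) {
      std::vector<double> fresh(n);
      for (int i = 0; i < n; ++i) fresh[i] = y[i] - mu;
      for (int j = 0; j < m; ++j) {
        if (beta[j] == 0.0) continue;
        const double* xj = Xp + (size_t) j * n;
        for (int i = 0; i < n; ++i) fresh[i] -= xj[i] * beta[j];
      }
      double maxdev = 0.0;
      for (int i = 0; i < n; ++i) {
        double dev = std::fabs(fresh[i] - e[i]);
        if (dev > maxdev) maxdev = dev;
        e[i] = fresh[i];
      }
      if (maxdev > resid_drift) resid_drift = maxdev;
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++n_kept;
      for (int j = 0; j < m; ++j) {
        beta_sum[j] += beta[j];
        incl_sum[j] += delta[j];
      }
      mu_sum += mu; pi_sum += pi; s2b_sum += s2b; s2e_sum += s2e;
      if (chain_at < n_chain) {
        pi_chain[chain_at] = pi; s2b_chain[chain_at] = s2b;
        s2e_chain[chain_at] = s2e; mu_chain[chain_at] = mu;
        if (keep_beta_chain)
          for (int j = 0; j < m; ++j) beta_chain(chain_at, j) = beta[j];
        ++chain_at;
      }
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector beta_mean(m), incl_freq(m);
  for (int j = 0; j < m; ++j) {
    beta_mean[j] = beta_sum[j] / n_kept;
    incl_freq[j] = incl_sum[j] / n_kept;
  }
  return List::create(
      _["beta_mean"] = beta_mean, _["inclusion_freq"] = incl_freq,
      _["mu_mean"] = mu_sum / n_kept, _["pi_mean"] = pi_sum / n_kept,
      _["sigma2_beta_mean"] = s2b_sum / n_kept,
      _["sigma2_e_mean"] = s2e_sum / n_kept,
      _["pi_chain"] = pi_chain, _["sigma2_beta_chain"] = s2b_chain,
      _["sigma2_e_chain"] = s2e_chain, _["mu_chain"] = mu_chain,
      _["beta_chain"] = beta_chain,
      _["n_kept"] = n_kept, _["resid_drift"] = resid_drift,
      _["m_used"] = m_used);
}
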