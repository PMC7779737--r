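#include <Rcpp.h>
using namespace Rcpp;

// MCMC for the Besag-York-Mollie model
//   c_i ~ Poisson(e_i * RR_i),  log RR_i = mu + s_i + v_i
//   s   ~ intrinsic CAR (conditional mean = neighbour average,
//         conditional precision = tau_s * f_i), sum-to-zero per
//         connected component (recentred every sweep)
//   v_i ~ N(0, 1/tau_v)
//   tau_s ~ Gamma(a_s, b_s), tau_v ~ Gamma(a_v, b_v)  (conjugate Gibbs)
//   mu flat; Gibbs via exp(mu) | rest ~ Gamma(C, sum_i e_i exp(s_i+v_i))
// s_i and v_i use adaptive random-walk Metropolis (tuned during burn-in
// toward ~44% acceptance). Uses R's RNG: deterministic under set.seed().
// [[Rcpp::export]]
List bym_mcmc(const IntegerVector& cases, const NumericVector& expected,
              const List& nbr, const IntegerVector& comp,
              int n_burn, int n_keep, int thin,
              double a_s, double b_s, double a_v, double b_v) {
  int H = cases.size();
  int n_comp = 0;
  for (int i = 0; i < H; ++i) if (comp[i] > n_comp) n_comp = comp[i];

  std::vector<std::vector<int>> nb(H);
  for (int i = 0; i < H; ++i) {
    IntegerVector v = nbr[i];
    for (int k = 0; k < v.size(); ++k) nb[i].push_back(v[k] - 1);
  }

  RNGScope scope;
  std::vector<double> s(H, 0.0), v(H, 0.0);
  double mu = 0.0, C_total = 0.0;
  for (int i = 0; i < H; ++i) C_total += cases[i];
  // crude initialisation at the smoothed log relative risk
  double e_total = 0.0;
  for (int i = 0; i < H; ++i) e_total += expected[i];
  mu = std::log((C_total + 0.5) / e_total);
  double tau_s = 1.0, tau_v = 1.0;
  std::vector<double> step_s(H, 0.3), step_v(H, 0.3);
  std::vector<int> acc_s(H, 0), acc_v(H, 0);

  int total_iter = n_burn + n_keep * thin;
  NumericMatrix logrr_draws(H, n_keep);
  NumericVector mu_draws(n_keep), tau_s_draws(n_keep), tau_v_draws(n_keep);
  int kept = 0, adapt_window = 100;

  for (int iter = 0; iter < total_iter; ++iter) {
    // --- spatial effects: single-site RW-MH under the ICAR full
    //     conditional N(mean of neighbours, 1/(tau_s * f_i))
    for (int i = 0; i < H; ++i) {
      int fi = nb[i].size();
      if (fi == 0) { s[i] = 0.0; continue; }    // islands carry no s
      double nbr_sum = 0.0;
      for (int j : nb[i]) nbr_sum += s[j];
      double prior_mean = nbr_sum / fi;
      double prop = s[i] + step_s[i] * norm_rand();
      double lam0 = expected[i] * std::exp(mu + s[i] + v[i]);
      double lam1 = expected[i] * std::exp(mu + prop + v[i]);
      double logratio = cases[i] * (prop - s[i]) - (lam1 - lam0)
        - 0.5 * tau_s * fi * ((prop - prior_mean) * (prop - prior_mean)
                              - (s[i] - prior_mean) * (s[i] - prior_mean));
      if (std::log(unif_rand()) < logratio) { s[i] = prop; acc_s[i]++; }
    }
    // recentre s within each connected component (sum-to-zero)
    {
      std::vector<double> msum(n_comp, 0.0);
      std::vector<int> mcnt(n_comp, 0);
      for (int i = 0; i < H; ++i) {
        if (nb[i].empty()) continue;
        msum[comp[i] - 1] += s[i];
        mcnt[comp[i] - 1]++;
      }
      for (int i = 0; i < H; ++i) {
        if (nb[i].empty()) continue;
        int c = comp[i] - 1;
        if (mcnt[c] > 0) s[i] -= msum[c] / mcnt[c];
      }
    }
    // --- exchangeable effects
    for (int i = 0; i < H; ++i) {
      double prop = v[i] + step_v[i] * norm_rand();
      double lam0 = expected[i] * std::exp(mu + s[i] + v[i]);
      double lam1 = expected[i] * std::exp(mu + s[i] + prop);
      double logratio = cases[i] * (prop - v[i]) - (lam1 - lam0)
        - 0.5 * tau_v * (prop * prop - v[i] * v[i]);
      if (std::log(unif_rand()) < logratio) { v[i] = prop; acc_v[i]++; }
    }
    // --- intercept: exp(mu) | rest ~ Gamma(C, rate) under a flat prior
    {
      double rate = 0.0;
      for (int i = 0; i < H; ++i)
        rate += expected[i] * std::exp(s[i] + v[i]);
      double shape = C_total > 0 ? C_total : 0.5;
      mu = std::log(R::rgamma(shape, 1.0 / rate));
    }
    // --- precisions: conjugate Gibbs
    {
      double ss = 0.0;
      int n_free = 0;
      for (int i = 0; i < H; ++i) {
        if (nb[i].empty()) continue;
        n_free++;
        for (int j : nb[i]) if (j > i) ss += (s[i] - s[j]) * (s[i] - s[j]);
      }
      // ICAR rank deficiency: one constraint per connected component
      tau_s = R::rgamma(a_s + 0.5 * (n_free - n_comp), 1.0 / (b_s + 0.5 * ss));
      double sv = 0.0;
      for (int i = 0; i < H; ++i) sv += v[i] * v[i];
      tau_v = R::rgamma(a_v + 0.5 * H, 1.0 / (b_v + 0.5 * sv));
    }
    // --- proposal adaptation during burn-in
    if (iter < n_burn && (iter + 1) % adapt_window == 0) {
      for (int i = 0; i < H; ++i) {
        double ra = (double)acc_s[i] / adapt_window;
        if (ra > 0.5) step_s[i] *= 1.3; else if (ra < 0.3) step_s[i] *= 0.7;
        ra = (double)acc_v[i] / adapt_window;
        if (ra > 0.5) step_v[i] *= 1.3; else if (ra < 0.3) step_v[i] *= 0.7;
        acc_s[i] = acc_v[i] = 0;
      }
    }
    // --- store
    if (iter >= n_burn && (iter - n_burn) % thin == 0 && kept < n_keep) {
      for (int i = 0; i < H; ++i) logrr_draws(i, kept) = mu + s[i] + v[i];
      mu_draws[kept] = mu;
      tau_s_draws[kept] = tau_s;
      tau_v_draws[kept] = tau_v;
      kept++;
    }
  }
  double acc_rate_s = 0.0, acc_rate_v = 0.0;
  int denom = total_iter - (n_burn / adapt_window) * adapt_window;
  if (denom < 1) denom = total_iter;
  for (int i = 0; i < H; ++i) {
    acc_rate_s += (double)acc_s[i] / denom / H;
    acc_rate_v += (double)acc_v[i] / denom / H;
  }
  return List::create(
    _["logrr"] = logrr_draws, _["mu"] = mu_draws,
    _["tau_s"] = tau_s_draws, _["tau_v"] = tau_v_draws,
    _["accept_s"] = acc_rate_s, _["accept_v"] = acc_rate_v);
}
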