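#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Random-walk Metropolis-within-Gibbs sampler for the gated 1-PL mixture.
//
// Parameters: theta_t[m] ~ N(0,1), theta_c[m] ~ N(mu_c, var_c), b[i] ~ N(0,1).
// The cheater indicator T_m = 1{theta_t[m] < theta_c[m]} is deterministic
// given the ability pair; a student's likelihood uses theta_t on secure
// items and, when T_m = 1, theta_c on exposed items.
//
// With discrimination fixed at 1, a student's log-likelihood over an item
// set is sum_i y_i z_i - softplus(z_i) with z_i = a - b_i, so a shift in the
// ability a enters the MH delta only through the count of correct answers
// and the softplus sums; the same holds per item over students. The loops
// below therefore run on per-student / per-item correct counts plus cached
// softplus sums, never touching the response matrix.
//
// Proposal scales are per-parameter, adapted in batches of 50 iterations
// during burn-in toward a 30-45% acceptance rate, then frozen.
// [[Rcpp::export]]
List dgm_sampler(IntegerMatrix Y, IntegerVector exposed,
                 int n_iter, int burn_in, int thin,
                 double proposal_scale, double mu_c, double var_c,
                 Nullable<NumericVector> fixed_b = R_NilValue) {
  const int M = Y.nrow(), I = Y.ncol();
  const bool b_fixed = fixed_b.isNotNull();
  const double sd_c = std::sqrt(var_c);

  std::vector<int> exp_idx, sec_idx;
  for (int i = 0; i < I; ++i) (exposed[i] ? exp_idx : sec_idx).push_back(i);
  const int nE = exp_idx.size(), nS = sec_idx.size();

  // sufficient counts: correct secure / exposed answers per student,
  // correct answers per item
  std::vector<double> Sm(M, 0.0), Em(M, 0.0), Ci(I, 0.0);
  for (int m = 0; m < M; ++m) {
    for (int k = 0; k < nS; ++k) Sm[m] += Y(m, sec_idx[k]);
    for (int k = 0; k < nE; ++k) Em[m] += Y(m, exp_idx[k]);
  }
  for (int i = 0; i < I; ++i)
    for (int m = 0; m < M; ++m) Ci[i] += Y(m, i);

  // crude moment-based initial values (clamped empirical logits)
  std::vector<double> tt(M), tc(M), b(I);
  if (b_fixed) {
    NumericVector fb(fixed_b);
    for (int i = 0; i < I; ++i) b[i] = fb[i];
  } else {
    for (int i = 0; i < I; ++i) {
      double p = std::min(std::max(Ci[i] / M, 0.5 / M), 1.0 - 0.5 / M);
      b[i] = -std::log(p / (1.0 - p));
    }
  }
  for (int m = 0; m < M; ++m) {
    double ps = std::min(std::max(Sm[m] / nS, 0.02), 0.98);
    double pe = nE ? std::min(std::max(Em[m] / nE, 0.02), 0.98) : 0.5;
    tt[m] = std::log(ps / (1.0 - ps));
    tc[m] = std::log(pe / (1.0 - pe));
  }

  std::vector<double> bs(nS), be(nE);   // difficulties split by item class

  // softplus sums over an item class at ability a
  auto sp_sec = [&](double a) {
    double s = 0.0;
    for (int k = 0; k < nS; ++k) s += softplus(a - bs[k]);
    return s;
  };
  auto sp_exp = [&](double a) {
    double s = 0.0;
    for (int k = 0; k < nE; ++k) s += softplus(a - be[k]);
    return s;
  };

  std::vector<double> s_tt(M, proposal_scale), s_tc(M, proposal_scale),
                      s_b(I, proposal_scale);
  std::vector<int> a_tt(M, 0), a_tc(M, 0), a_b(I, 0);

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws_tt(n_keep, M), draws_tc(n_keep, M), draws_b(n_keep, I);
  std::vector<int> t_sum(M, 0);
  int kept = 0;
  long long acc_tot = 0, prop_tot = 0;

  std::vector<double> sp_sec_cur(M), sp_exp_cur(M), eff(M);

  for (int iter = 1; iter <= n_iter; ++iter) {
    // refresh caches (b changed in the previous sweep)
    for (int k = 0; k < nS; ++k) bs[k] = b[sec_idx[k]];
    for (int k = 0; k < nE; ++k) be[k] = b[exp_idx[k]];
    for (int m = 0; m < M; ++m) {
      eff[m] = (tt[m] < tc[m]) ? tc[m] : tt[m];
      sp_sec_cur[m] = sp_sec(tt[m]);
      sp_exp_cur[m] = sp_exp(eff[m]);
    }

    // theta_t updates
    for (int m = 0; m < M; ++m) {
      double prop = tt[m] + s_tt[m] * R::norm_rand();
      double sp_new = sp_sec(prop);
      double lr = (prop - tt[m]) * Sm[m] - (sp_new - sp_sec_cur[m])
                + 0.5 * (tt[m] * tt[m] - prop * prop);  // N(0,1) prior
      double eff_new = (prop < tc[m]) ? tc[m] : prop;
      double spe_new = sp_exp_cur[m];
      if (eff_new != eff[m]) {
        spe_new = sp_exp(eff_new);
        lr += (eff_new - eff[m]) * Em[m] - (spe_new - sp_exp_cur[m]);
      }
      if (std::log(R::unif_rand()) < lr) {
        tt[m] = prop; sp_sec_cur[m] = sp_new;
        eff[m] = eff_new; sp_exp_cur[m] = spe_new;
        ++a_tt[m]; ++acc_tot;
      }
      ++prop_tot;
    }

    // theta_c updates (exposed items only carry theta_c information)
    for (int m = 0; m < M; ++m) {
      double prop = tc[m] + s_tc[m] * R::norm_rand();
      double eff_new = (tt[m] < prop) ? prop : tt[m];
      double zo = (tc[m] - mu_c) / sd_c, zn = (prop - mu_c) / sd_c;
      double lr = 0.5 * (zo * zo - zn * zn);
      double spe_new = sp_exp_cur[m];
      if (eff_new != eff[m]) {
        spe_new = sp_exp(eff_new);
        lr += (eff_new - eff[m]) * Em[m] - (spe_new - sp_exp_cur[m]);
      }
      if (std::log(R::unif_rand()) < lr) {
        tc[m] = prop; eff[m] = eff_new; sp_exp_cur[m] = spe_new;
        ++a_tc[m]; ++acc_tot;
      }
      ++prop_tot;
    }

    // difficulty updates, against each student's current effective ability
    for (int i = 0; !b_fixed && i < I; ++i) {
      double prop = b[i] + s_b[i] * R::norm_rand();
      double sp_diff = 0.0;
      if (exposed[i]) {
        for (int m = 0; m < M; ++m)
          sp_diff += softplus(eff[m] - prop) - softplus(eff[m] - b[i]);
      } else {
        for (int m = 0; m < M; ++m)
          sp_diff += softplus(tt[m] - prop) - softplus(tt[m] - b[i]);
      }
      double lr = -(prop - b[i]) * Ci[i] - sp_diff
                + 0.5 * (b[i] * b[i] - prop * prop);  // N(0,1) prior
      if (std::log(R::unif_rand()) < lr) { b[i] = prop; ++a_b[i]; ++acc_tot; }
      ++prop_tot;
    }

    // batch adaptation during burn-in only (frozen afterwards)
    if (iter <= burn_in && iter % 50 == 0) {
      const double target = 0.375;
      auto tune = [&](std::vector<double>& s, std::vector<int>& a, int n) {
        for (int j = 0; j < n; ++j) {
          s[j] = std::min(std::max(
            s[j] * std::exp(a[j] / 50.0 - target), 0.02), 10.0);
          a[j] = 0;
        }
      };
      tune(s_tt, a_tt, M); tune(s_tc, a_tc, M); tune(s_b, a_b, I);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0 && kept < n_keep) {
      for (int m = 0; m < M; ++m) {
        draws_tt(kept, m) = tt[m];
        draws_tc(kept, m) = tc[m];
        if (tt[m] < tc[m]) ++t_sum[m];
      }
      for (int i = 0; i < I; ++i) draws_b(kept, i) = b[i];
      ++kept;
    }
  }

  NumericVector p_cheater(M);
  for (int m = 0; m < M; ++m) p_cheater[m] = (double)t_sum[m] / kept;

  return List::create(_["p_cheater"] = p_cheater,
                      _["draws_theta_t"] = draws_tt,
                      _["draws_theta_c"] = draws_tc,
                      _["draws_b"] = draws_b,
                      _["retained_draws"] = kept,
                      _["acceptance_rate"] = (double)acc_tot / prop_tot);
}
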