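# Independent oracles used across tests. These deliberately avoid the code
# paths they check: plain-R quadrature, brute-force scans, closed forms.

# Exact posterior P(theta_t < theta_c | y) for a single student with KNOWN
# item difficulties, by dense 2-D grid integration over (theta_t, theta_c).
# Priors: theta_t ~ N(0,1), theta_c ~ N(mu_c, sqrt(var_c)); likelihood uses
# theta_t on secure items and, when theta_t < theta_c, theta_c on exposed
# items (otherwise theta_t).
quadrature_p_cheater <- function(y, b, exposed, mu_c = 1, var_c = 2,
                                 n_grid = 401) {
  tt <- seq(-8, 8, length.out = n_grid)
  tc <- seq(mu_c - 8 * sqrt(var_c), mu_c + 8 * sqrt(var_c),
            length.out = n_grid)
  sec <- which(exposed == 0); expo <- which(exposed == 1)
  ll_ability <- function(a, idx) {   # log-lik of item subset at ability a
    vapply(a, function(ai) {
      p <- stats::plogis(ai - b[idx])
      sum(y[idx] * log(p) + (1 - y[idx]) * log(1 - p))
    }, 0)
  }
  ll_sec_tt <- ll_ability(tt, sec)       # per tt value
  ll_exp_tt <- ll_ability(tt, expo)      # exposed under honest mode
  ll_exp_tc <- ll_ability(tc, expo)      # exposed under cheater mode
  lp_tt <- stats::dnorm(tt, log = TRUE)
  lp_tc <- stats::dnorm(tc, mu_c, sqrt(var_c), log = TRUE)
  # joint log density on the grid: outer over (tt, tc)
  gate <- outer(tt, tc, `<`)
  lj <- outer(ll_sec_tt + lp_tt, lp_tc, `+`) +
    ifelse(gate, outer(rep(0, length(tt)), ll_exp_tc, `+`),
           outer(ll_exp_tt, rep(0, length(tc)), `+`))
  w <- exp(lj - max(lj))
  sum(w[gate]) / sum(w)
}

# Brute-force entropy scan over all midpoint candidates (naive loops).
brute_force_cutoff <- function(p, truth) {
  h <- function(v) {
    if (!length(v)) return(0)
    q <- mean(v)
    if (q %in% c(0, 1)) return(0)
    -q * log2(q) - (1 - q) * log2(1 - q)
  }
  u <- sort(unique(p))
  cands <- (u[-length(u)] + u[-1]) / 2
  ents <- numeric(length(cands))
  for (j in seq_along(cands)) {
    l <- truth[p <= cands[j]]; r <- truth[p > cands[j]]
    ents[j] <- (length(l) * h(l) + length(r) * h(r)) / length(truth)
  }
  best <- max(cands[ents <= min(ents) + 1e-12])
  list(cutoff = best, entropy = min(ents),
       candidates = cands, entropies = ents)
}

# Fine 3-D trapezoid-style quadrature for the true-prevalence posterior,
# independent of the package's tensor-grid marginalization.
brute_force_tp_mean <- function(k, n, sen_bounds, spe_bounds, n_grid = 300) {
  tp <- seq(0, 1, length.out = n_grid)
  sen <- if (sen_bounds[1] == sen_bounds[2]) sen_bounds[1] else
    seq(sen_bounds[1], sen_bounds[2], length.out = n_grid)
  spe <- if (spe_bounds[1] == spe_bounds[2]) spe_bounds[1] else
    seq(spe_bounds[1], spe_bounds[2], length.out = n_grid)
  post <- numeric(length(tp))
  for (j in seq_along(tp)) {
    acc <- 0
    for (s in sen) acc <- acc + sum(stats::dbinom(k, n, pmin(pmax(
      tp[j] * s + (1 - tp[j]) * (1 - spe), 0), 1)))
    post[j] <- acc
  }
  sum(post * tp) / sum(post)
}

# small deterministic exam for fast pipeline tests
tiny_exam <- function(seed = 7, prop = 0.3, efficacy = "high",
                      n_students = 60, n_items = 30, n_exposed = 8) {
  simulate_exam(scenario_config(prop, efficacy, n_students = n_students,
                                n_items = n_items, n_exposed = n_exposed),
                seed = seed)
}
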