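# Shared fixtures and independent oracles. Everything is built in code at
# test time; no stored data.

# Small simulated choice set for one participant-session.
sim_trials <- function(k = 0.01, s = 1.5, beta_temp = 1, repeats = 2,
                       seed = 7) {
  par <- discount_params("generalized_hyperbolic", k = k, s = s,
                         beta_temp = beta_temp)
  des <- make_choice_design(repeats = repeats, seed = seed)
  simulate_choices(par, des, seed = seed + 1)
}

# Closed-form normalized AUC of the generalized hyperbolic discount curve:
# integral of (1+kd)^(-s) over [0, D], divided by D.
auc_closed_form <- function(k, s, max_delay = 180) {
  if (s == 1) log1p(k * max_delay) / (k * max_delay)
  else ((1 + k * max_delay)^(1 - s) - 1) / (k * (1 - s) * max_delay)
}

# Exact one-tailed Mann-Whitney p (alternative: x stochastically greater
# than y) by enumerating all C(n1+n2, n1) group assignments of the pooled
# sample. Mid-ranks make it valid under ties.
mw_exact_p_greater <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  mean(u_all >= u_obs - 1e-9)
}

# Dense-grid posterior machinery for the 2-parameter hyperbolic model:
# the independent oracle for exact LOO and for validating the MCMC draws.
hyperbolic_grid <- function(trials, prior_sd = 2.5, prior_mean = c(0, 0),
                            logk = seq(-9, 2, length.out = 240),
                            logbt = seq(-4, 3, length.out = 200)) {
  g <- expand.grid(logk = logk, logbt = logbt)
  # pointwise log-likelihood, grid points x trials
  ll <- matrix(NA_real_, nrow(g), nrow(trials))
  for (i in seq_len(nrow(trials))) {
    sv <- trials$reward_ll[i] / (1 + exp(g$logk) * trials$delay[i])
    p <- plogis(exp(g$logbt) * (sv - 10))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll[, i] <- if (trials$choice[i] == "LL") log(p) else log1p(-p)
  }
  lprior <- dnorm(g$logk, prior_mean[1], prior_sd, log = TRUE) +
    dnorm(g$logbt, prior_mean[2], prior_sd, log = TRUE)
  list(grid = g, ll = ll, lprior = lprior)
}

# Exact leave-one-out elpd by grid refitting: for each trial i the
# held-out posterior is exp(sum(ll[,-i]) + lprior) renormalized, and
# elpd_i = log E_{-i}[p(y_i | theta)].
grid_exact_loo <- function(gp) {
  ll_tot <- rowSums(gp$ll)
  vapply(seq_len(ncol(gp$ll)), function(i) {
    lw <- ll_tot - gp$ll[, i] + gp$lprior
    lw <- lw - max(lw)
    w <- exp(lw) / sum(exp(lw))
    log(sum(w * exp(gp$ll[, i])))
  }, 0)
}

# iid draws (row indices) from the full-data grid posterior.
grid_posterior_draws <- function(gp, n, seed) {
  set.seed(seed)
  lw <- rowSums(gp$ll) + gp$lprior
  lw <- lw - max(lw)
  sample.int(nrow(gp$grid), n, replace = TRUE, prob = exp(lw))
}

# All permutations of 1..n as a list (n small).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(combinat_perms(n - 1), function(p) c(i, setdiff(seq_len(n), i)[p]))
  }))
}

# Direct convolution design-matrix oracle, independent of build_design:
# plain double-loop discrete convolution on the microtime grid.
oracle_condition_column <- function(events, tr, n_scans, microtime_bins = 16) {
  dt <- tr / microtime_bins
  n_fine <- n_scans * microtime_bins
  g <- numeric(n_fine)
  for (r in seq_len(nrow(events))) {
    i0 <- floor(events$onset_s[r] / dt) + 1
    nbin <- max(1, round(events$duration_s[r] / dt))
    for (j in i0:min(n_fine, i0 + nbin - 1)) g[j] <- g[j] + 1
  }
  h <- canonical_hrf(dt)
  out <- numeric(n_fine)
  for (t in seq_len(n_fine)) {
    jmax <- min(t, length(h))
    out[t] <- sum(h[seq_len(jmax)] * g[t - seq_len(jmax) + 1])
  }
  out[(seq_len(n_scans) - 1) * microtime_bins + 1]
}
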