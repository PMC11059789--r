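# Independent oracles and tiny fixture builders used across tests.

# Efron-approximation partial log-likelihood for counting-process data with
# a single covariate, written directly from the definition (independent of
# the fitting route).
efron_partial_loglik <- function(beta, start, stop, event, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(stop[event == 1]))) {
    at_risk <- start < t & t <= stop
    dead <- at_risk & event == 1 & stop == t
    d <- sum(dead)
    sum_risk <- sum(exp(eta[at_risk]))
    sum_dead <- sum(exp(eta[dead]))
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1L)
      ll <- ll - log(sum_risk - (l / d) * sum_dead)
  }
  ll
}

grid_mle <- function(start, stop, event, x, grid = seq(-3, 3, by = 1e-3)) {
  ll <- vapply(grid, efron_partial_loglik, numeric(1),
               start = start, stop = stop, event = event, x = x)
  grid[which.max(ll)]
}

# DerSimonian-Laird pooling written out long-hand (spreadsheet style).
dl_by_hand <- function(est, se) {
  w <- 1 / se^2
  b_fe <- sum(w * est) / sum(w)
  Q <- sum(w * (est - b_fe)^2)
  k <- length(est)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  list(est = sum(wr * est) / sum(wr), se = sqrt(1 / sum(wr)), tau2 = tau2)
}

# Subject records with explicit fields, for counting-process tests.
make_subjects <- function(times, events, arms, ids = NULL) {
  data.frame(subject_id = if (is.null(ids)) sprintf("s%03d", seq_along(times)) else ids,
             trial_id = "T1", formulation = "lai_1m",
             arm = arms, time_days = as.integer(times),
             event = as.integer(events))
}

# Small one-trial simulation used by several calibration tests.
sim_one_trial <- function(n_per_arm, horizon, spec, params, seed,
                          dropout = 0) {
  d <- trial_design("T1", params$name, n_per_arm, n_per_arm, horizon,
                    dropout_hazard_per_day = dropout)
  simulate_trial(d, params, spec, seed = seed)
}
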