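# Shared fixtures and independent oracles.

# random-but-reproducible parameter sets spanning the regimes the model is
# used in (strong/weak zero inflation, small/large burst size)
random_zinb_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i)
      zinb_params(omega = runif(1, 0.01, 0.95),
                  r = runif(1, 0.1, 8),
                  p = runif(1, 0.05, 0.95)))
  })
}

# moments by brute-force summation of the tabulated pmf (truncated where
# the tail mass is below 1e-12) -- independent of the closed forms
moments_by_summation <- function(params) {
  nm <- zinb_support_bound(params, tail = 1e-12)
  pv <- zinb_pmf_vector(params, nm)
  n <- seq_along(pv) - 1
  m <- sum(n * pv)
  list(mean = m, variance = sum(n^2 * pv) - m^2)
}

# naive per-cell log-likelihood (no histogram shortcut)
naive_log_likelihood <- function(x, params) {
  sum(vapply(x, function(k) zinb_log_pmf(params, k), 0))
}

# time-weighted average of a trajectory's mRNA level over [t_from, t_end]
trajectory_time_average <- function(tr, t_from = 0) {
  t <- c(tr$times, tr$t_end)
  keep <- t[-1] > t_from
  lo <- pmax(t[-length(t)], t_from)[keep]
  hi <- t[-1][keep]
  sum(tr$mrna[keep] * (hi - lo)) / (tr$t_end - t_from)
}

# time-weighted promoter-state occupancy over the whole trajectory
trajectory_state_occupancy <- function(tr) {
  t <- c(tr$times, tr$t_end)
  dt <- diff(t)
  vapply(c("C", "B", "A"), function(s) sum(dt[tr$states == s]) / tr$t_end, 0)
}

# empirical total-variation distance between a count sample and a pmf
tv_distance <- function(counts, params) {
  nm <- max(counts, zinb_support_bound(params, tail = 1e-9))
  emp <- tabulate(counts + 1L, nbins = nm + 1L) / length(counts)
  th <- zinb_pmf_vector(params, nm)
  0.5 * sum(abs(emp - th)) + 0.5 * (1 - sum(th))
}

# wrap a bare matrix as a posterior_chain for diagnostic-function tests
as_pseudo_chain <- function(samples, lps = rep(0, nrow(samples))) {
  colnames(samples) <- c("omega", "r", "p")
  structure(list(samples = samples, log_posteriors = lps,
                 acceptance_rate = 0.5, settings = mcmc_settings(),
                 data_digest = "pseudo", warnings = character(0)),
            class = "posterior_chain")
}
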