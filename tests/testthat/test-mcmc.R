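# Likelihood, priors, the Metropolis-Hastings sampler and its diagnostics.

test_that("log-likelihood factorises and matches the naive sum", {
  pp <- zinb_params(0.5, 1, 0.5)
  # single zero count: log(omega + (1-omega)(1-p)^r)
  expect_equal(log_likelihood(0L, pp), log(0.75))
  # i.i.d. factorisation
  expect_equal(log_likelihood(c(1L, 1L), pp), 2 * log_likelihood(1L, pp))

  # histogram evaluation vs naive per-cell summation on random fixtures
  withr::with_seed(77, {
    for (i in 1:50) {
      pp_i <- zinb_params(runif(1, 0.05, 0.9), runif(1, 0.2, 5),
                          runif(1, 0.1, 0.9))
      x <- rnbinom(200, size = 2, mu = 5)
      expect_equal(log_likelihood(x, pp_i), naive_log_likelihood(x, pp_i),
                   tolerance = 1e-10)
    }
  })
})

test_that("priors are correct densities on the stated support", {
  s <- mcmc_settings()
  expect_equal(log_prior(zinb_params(0.5, 1, 0.5), s),
               log(2 * dnorm(1 / 20) / 20))
  expect_equal(log_prior(c(0.5, -0.1, 0.5), s), -Inf)
  expect_equal(log_prior(c(1.2, 1, 0.5), s), -Inf)
  # the half-normal prior on r integrates to 1
  dens <- function(r) exp(vapply(r, function(ri) log_prior(c(0.5, ri, 0.5), s), 0))
  expect_equal(integrate(dens, 0, Inf, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-6)
})

test_that("log-posterior is additive and propagates -Inf", {
  s <- mcmc_settings()
  pp <- zinb_params(0.4, 2, 0.6)
  x <- c(0L, 2L, 5L)
  expect_equal(log_posterior(x, pp, s),
               log_likelihood(x, pp) + log_prior(pp, s))
  expect_equal(log_posterior(x, c(0.4, 2, 1.5), s), -Inf)
  # doubling every count's multiplicity doubles the likelihood part
  lp1 <- log_posterior(x, pp, s) - log_prior(pp, s)
  lp2 <- log_posterior(c(x, x), pp, s) - log_prior(pp, s)
  expect_equal(lp2, 2 * lp1)
})

test_that("the chain is bit-reproducible under a fixed seed", {
  d <- sample_zinb(zinb_params(0.3, 2, 0.9), 300, seed = 1)
  s <- mcmc_settings(n_samples = 3000, burn_in = 500, thin = 5, seed = 9)
  c1 <- run_mcmc(d$count, s)
  c2 <- run_mcmc(d$count, s)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$log_posteriors, c2$log_posteriors)
  expect_gt(c1$acceptance_rate, 0)
  expect_lt(c1$acceptance_rate, 1)
})

test_that("with no data the corrected chain samples the prior", {
  # wider proposals than the production 5% rule: with no likelihood the
  # state-dependent walk would otherwise need very long chains to decorrelate
  s <- mcmc_settings(n_samples = 120000, burn_in = 20000, thin = 50,
                     proposal_scale = 0.5, seed = 13)
  ch <- run_mcmc(NULL, s)
  expect_equal(nrow(ch$samples), 2000)
  ks_omega <- suppressWarnings(ks.test(ch$samples[, "omega"], punif)$statistic)
  ks_p <- suppressWarnings(ks.test(ch$samples[, "p"], punif)$statistic)
  half_norm_cdf <- function(q) 2 * pnorm(q / 20) - 1
  ks_r <- suppressWarnings(ks.test(ch$samples[, "r"], half_norm_cdf)$statistic)
  expect_lt(ks_omega, 0.035)
  expect_lt(ks_p, 0.035)
  expect_lt(ks_r, 0.035)
  # prior-only equal-tailed interval for omega is close to (0.025, 0.975)
  ci <- credible_intervals(ch)
  expect_equal(unname(ci["omega", ]), c(0.025, 0.975), tolerance = 0.02)
})

test_that("credible intervals recover generating parameters", {
  gen <- zinb_params(0.3, 2, 0.9)
  d <- sample_zinb(gen, 2000, seed = 17)
  ch <- run_mcmc(d$count, mcmc_settings(n_samples = 50000, burn_in = 10000,
                                        thin = 10, seed = 18))
  ci <- credible_intervals(ch)
  expect_true(ci["omega", "low"] <= 0.3 && 0.3 <= ci["omega", "high"])
  expect_true(ci["r", "low"] <= 2 && 2 <= ci["r", "high"])
  expect_true(ci["p", "low"] <= 0.9 && 0.9 <= ci["p", "high"])
  # MAP sample lies inside every marginal interval it defines
  map <- map_estimate(ch)
  expect_true(ci["omega", 1] <= map$omega && map$omega <= ci["omega", 2])
  expect_true(ci["r", 1] <= map$r && map$r <= ci["r", 2])
  expect_true(ci["p", 1] <= map$p && map$p <= ci["p", 2])
})

test_that("MAP and interval edge cases", {
  one <- as_pseudo_chain(matrix(c(0.4, 2, 0.6), 1), lps = 1.5)
  m <- map_estimate(one)
  expect_equal(c(m$omega, m$r, m$p), c(0.4, 2, 0.6))

  const <- as_pseudo_chain(matrix(rep(c(0.4, 2, 0.6), each = 200), 200))
  ci <- credible_intervals(const)
  expect_equal(unname(ci[, "low"]), unname(ci[, "high"]))

  ci0 <- credible_intervals(const, level = 0)
  expect_equal(ci0[, "low"], ci0[, "high"])
})

test_that("fitted kinetics are monotone in the generating kinetics", {
  st <- function(seed) mcmc_settings(n_samples = 15000, burn_in = 3000,
                                     thin = 10, seed = seed)
  # three conditions differing only in r: fitted burst frequency ordered
  freqs <- vapply(seq_along(c(0.5, 2, 6)), function(i) {
    r <- c(0.5, 2, 6)[i]
    d <- sample_zinb(zinb_params(0.3, r, 0.8), 1500, seed = 50 + i)
    fit_condition(d$count, st(60 + i))$kinetics_map$burst_frequency
  }, 0)
  expect_true(all(diff(freqs) > 0))

  # two conditions differing only in p: fitted burst size ordered
  sizes <- vapply(1:2, function(i) {
    p <- c(0.5, 0.9)[i]
    d <- sample_zinb(zinb_params(0.3, 2, p), 1500, seed = 70 + i)
    fit_condition(d$count, st(80 + i))$kinetics_map$burst_size
  }, 0)
  expect_gt(sizes[2], sizes[1])

  # deterministic end to end
  d <- sample_zinb(zinb_params(0.3, 2, 0.8), 500, seed = 90)
  f1 <- fit_condition(d$count, st(91))
  f2 <- fit_condition(d$count, st(91))
  expect_identical(f1$chain$samples, f2$chain$samples)
  expect_equal(unclass(f1$map), unclass(f2$map))
})

test_that("the filter is applied before fitting", {
  d <- sample_zinb(zinb_params(0.3, 2, 0.8), 800, seed = 95)
  art <- inject_artifact_cells(d, 0.1, c(300, 600), seed = 96)
  fit <- fit_condition(art, mcmc_settings(n_samples = 5000, burn_in = 1000,
                                          thin = 10, seed = 97))
  expect_equal(fit$n_cells_filtered, length(provenance(art)$artifact_cells))
  expect_equal(fit$n_cells_used + fit$n_cells_filtered, 800)
})

test_that("convergence diagnostics match i.i.d. and AR(1) references", {
  n <- 4000
  iid <- withr::with_seed(101, matrix(runif(3 * n), n))
  rep_iid <- convergence_report(as_pseudo_chain(iid))
  expect_true(all(abs(rep_iid$ess - n) / n < 0.2))
  expect_true(all(rep_iid$split_rhat < 1.05))

  const <- as_pseudo_chain(matrix(rep(c(0.4, 2, 0.6), each = 300), 300))
  rep_const <- suppressMessages(convergence_report(const, quiet = TRUE))
  expect_true(all(rep_const$ess <= 2))
  expect_true(any(grepl("ESS", rep_const$flags)))

  rho <- 0.9
  ar1 <- withr::with_seed(103, {
    e <- matrix(rnorm(3 * n), n)
    x <- e
    for (i in 2:n) x[i, ] <- rho * x[i - 1, ] + sqrt(1 - rho^2) * e[i, ]
    x
  })
  rep_ar <- convergence_report(as_pseudo_chain(ar1), quiet = TRUE)
  target <- n * (1 - rho) / (1 + rho)
  expect_true(all(abs(rep_ar$ess - target) / target < 0.3))
})

test_that("resuming extends a chain from its last state", {
  d <- sample_zinb(zinb_params(0.3, 2, 0.8), 400, seed = 110)
  ch <- run_mcmc(d$count, mcmc_settings(n_samples = 4000, burn_in = 1000,
                                        thin = 10, seed = 111))
  more <- resume_mcmc(ch, d$count, n_samples = 2000, seed = 112)
  expect_equal(nrow(more$samples), nrow(ch$samples) + 200)
  expect_identical(more$samples[seq_len(nrow(ch$samples)), ], ch$samples)
})

test_that("paper-literal symmetric acceptance is available", {
  d <- sample_zinb(zinb_params(0.3, 2, 0.9), 500, seed = 120)
  s_sym <- mcmc_settings(n_samples = 4000, burn_in = 1000, thin = 10,
                         seed = 121, hastings_correction = FALSE)
  ch <- run_mcmc(d$count, s_sym)
  expect_equal(nrow(ch$samples), 300)
  expect_false(ch$settings$hastings_correction)
})
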