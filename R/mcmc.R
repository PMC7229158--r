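# Bayesian inference of (omega, r, p) from a filtered single-condition count
# sample: ZINB likelihood, uniform priors on omega and p, a positive
# half-normal prior on r, and a random-walk Metropolis-Hastings sampler whose
# proposal standard deviation is 5% of the current parameter values.

#' MCMC sampler settings
#'
#' Defaults follow the production configuration used for smFISH fits:
#' 500,000 samples with 100,000 discarded as burn-in and thinning by 100,
#' a multivariate Gaussian proposal with standard deviation 5% of the
#' current parameter values, and a half-Normal(0, 20) prior on `r`.
#'
#' Because the proposal scale depends on the current state the kernel is
#' asymmetric; with `hastings_correction = TRUE` (default) the acceptance
#' ratio includes the proposal-density correction so the chain targets the
#' posterior exactly.  `hastings_correction = FALSE` gives the plain
#' symmetric Metropolis rule for comparison.
#'
#' The `proposal_floor` puts a small absolute lower bound on the proposal
#' standard deviation so the chain cannot be absorbed near a parameter value
#' of zero, where 5%-of-current would collapse the step size.
#'
#' @param n_samples Total iterations.
#' @param burn_in Iterations discarded from the front.
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param proposal_scale Proposal SD as a fraction of the current value.
#' @param proposal_floor Absolute lower bound on the proposal SD.
#' @param seed Integer seed; the whole chain is reproducible.
#' @param prior_r_sigma Scale of the half-normal prior on `r`.
#' @param hastings_correction Apply the asymmetric-proposal correction.
#' @param init Optional numeric `c(omega, r, p)` start; default is a
#'   method-of-moments start (see [run_mcmc()]).
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_samples = 500000, burn_in = 100000, thin = 100,
                          proposal_scale = 0.05, proposal_floor = 1e-4,
                          seed = 1, prior_r_sigma = 20,
                          hastings_correction = TRUE, init = NULL) {
  stopifnot(burn_in < n_samples, thin >= 1, proposal_scale > 0,
            proposal_floor >= 0, prior_r_sigma > 0)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 proposal_scale = proposal_scale,
                 proposal_floor = proposal_floor, seed = seed,
                 prior_r_sigma = prior_r_sigma,
                 hastings_correction = isTRUE(hastings_correction),
                 init = init),
            class = "mcmc_settings")
}

# --- likelihood ------------------------------------------------------------

count_vector <- function(counts) {
  if (is.null(counts)) return(integer(0))
  x <- if (is_count_dataset(counts)) {
    if (length(unique(counts$condition)) > 1)
      stop("fit one condition at a time", call. = FALSE)
    counts$count
  } else as.integer(counts)
  if (length(x) > 0 && (any(x < 0) || any(is.na(x))))
    stop("counts must be non-negative integers", call. = FALSE)
  x
}

# histogram form: unique counts and multiplicities make each likelihood
# evaluation O(number of distinct counts), not O(cells)
count_histogram <- function(x) {
  tab <- table(x)
  list(k = as.integer(names(tab)), w = as.numeric(tab))
}

#' Log-likelihood of a count sample under the ZINB model
#'
#' `sum_i log P(n_i | theta)`, evaluated through the count histogram
#' (`sum_k multiplicity(k) * log P(k)`) so the cost per evaluation scales
#' with the number of distinct counts rather than the number of cells.
#'
#' @param counts A single-condition [count_dataset()] or an integer vector
#'   of per-cell counts (already filtered).
#' @param params A [zinb_params()] object.
#' @return The log-likelihood (`-Inf` if any observed count has zero
#'   probability).
#' @export
log_likelihood <- function(counts, params) {
  x <- count_vector(counts)
  if (length(x) == 0) stop("'counts' is empty", call. = FALSE)
  h <- count_histogram(x)
  sum(h$w * zinb_log_pmf(params, h$k))
}

# --- prior and posterior ---------------------------------------------------

# theta = c(omega, r, p); support is (0,1) x (0,Inf) x (0,1)
log_prior_theta <- function(theta, prior_r_sigma) {
  if (theta[1] <= 0 || theta[1] >= 1 || theta[2] <= 0 ||
      theta[3] <= 0 || theta[3] >= 1) return(-Inf)
  # half-normal on r: twice the N(0, sigma) density, truncated to r > 0
  log(2) + stats::dnorm(theta[2], 0, prior_r_sigma, log = TRUE)
}

#' Log prior density
#'
#' Uniform(0,1) priors on `omega` and `p`; a half-Normal(0,
#' `prior_r_sigma`) prior on `r`, truncated to positive values (its density
#' is twice the corresponding normal density).
#'
#' @param params A [zinb_params()] object or a numeric `c(omega, r, p)`.
#' @param settings An [mcmc_settings()] object (only `prior_r_sigma` is
#'   used).
#' @return Log prior density (`-Inf` outside the support).
#' @export
log_prior <- function(params, settings = mcmc_settings()) {
  theta <- if (inherits(params, "zinb_params"))
    c(params$omega, params$r, params$p) else as.numeric(params)
  stopifnot(length(theta) == 3)
  log_prior_theta(theta, settings$prior_r_sigma)
}

#' Unnormalised log posterior
#'
#' @inheritParams log_prior
#' @param counts As in [log_likelihood()]; `NULL` gives the prior alone
#'   (useful for sampler validation).
#' @return `log_likelihood + log_prior` (up to the evidence constant);
#'   `-Inf` propagates from either term.
#' @export
log_posterior <- function(counts, params, settings = mcmc_settings()) {
  lp <- log_prior(params, settings)
  if (!is.finite(lp)) return(-Inf)
  if (is.null(counts) || length(count_vector(counts)) == 0) return(lp)
  lp + log_likelihood(counts, params)
}

# fast in-sampler versions working on a precomputed histogram
make_loglik_fn <- function(h) {
  if (length(h$k) == 0) return(function(theta) 0)
  has_zero <- h$k[1] == 0L
  w0 <- if (has_zero) h$w[1] else 0
  kp <- if (has_zero) h$k[-1] else h$k
  wp <- if (has_zero) h$w[-1] else h$w
  lgf <- lgamma(kp + 1)
  function(theta) {
    omega <- theta[1]; r <- theta[2]; p <- theta[3]
    l1mp <- log1p(-p)
    ll <- 0
    if (w0 > 0) {
      a <- log(omega); b <- log1p(-omega) + r * l1mp
      m <- max(a, b)
      ll <- w0 * (m + log(exp(a - m) + exp(b - m)))
    }
    if (length(kp) > 0) {
      ll <- ll + sum(wp * (log1p(-omega) + lgamma(kp + r) - lgamma(r) - lgf +
                             r * l1mp + kp * log(p)))
    }
    ll
  }
}

# method-of-moments start: r, p from the mean/variance of the positive
# counts, omega from the excess of zeros over the fitted NB's zero mass
moment_init <- function(x) {
  pos <- x[x > 0]
  if (length(pos) < 2) return(c(0.5, 1, 0.5))
  mp <- mean(pos); vp <- stats::var(pos)
  b <- max(vp / mp - 1, 0.1)
  p <- b / (1 + b)
  r <- max(mp / b, 1e-3)
  p0_nb <- exp(r * log1p(-p))
  z <- mean(x == 0)
  omega <- (z - p0_nb) / (1 - p0_nb)
  c(min(max(omega, 0.01), 0.99), r, min(max(p, 0.01), 0.99))
}

#' Run the Metropolis-Hastings sampler
#'
#' Random-walk sampler for `theta = (omega, r, p)` targeting the posterior.
#' The proposal is diagonal Gaussian with standard deviation
#' `max(proposal_scale * theta_i, proposal_floor)` evaluated at the current
#' state; because that scale moves with the state, the acceptance ratio
#' includes the reverse/forward proposal-density correction by default
#' (see [mcmc_settings()]).  Out-of-support proposals are rejected.
#'
#' With `counts = NULL` the likelihood is identically zero and the chain
#' samples the prior — a standard sampler-correctness check.
#'
#' @param counts A single-condition [count_dataset()] or integer vector,
#'   already filtered of artifact cells; or `NULL` for prior-only sampling.
#' @param settings An [mcmc_settings()] object.
#' @return A `posterior_chain`: list with `samples` (matrix, columns
#'   `omega`, `r`, `p`; post-burn-in, thinned), `log_posteriors`,
#'   `acceptance_rate`, `settings`, `data_digest` and `warnings`.
#' @examples
#' d <- sample_zinb(zinb_params(0.3, 2, 0.9), 500, seed = 1)
#' ch <- run_mcmc(d, mcmc_settings(n_samples = 2000, burn_in = 500, thin = 5,
#'                                 seed = 2))
#' map_estimate(ch)
#' @export
run_mcmc <- function(counts, settings = mcmc_settings()) {
  stopifnot(inherits(settings, "mcmc_settings"))
  x <- count_vector(counts)
  h <- count_histogram(x)
  loglik <- make_loglik_fn(h)
  sigma_r <- settings$prior_r_sigma
  scale <- settings$proposal_scale
  floor_sd <- settings$proposal_floor
  hastings <- settings$hastings_correction

  n_keep <- (settings$n_samples - settings$burn_in) %/% settings$thin
  samples <- matrix(NA_real_, n_keep, 3,
                    dimnames = list(NULL, c("omega", "r", "p")))
  lps <- numeric(n_keep)

  res <- local_seed(settings$seed, {
    theta <- settings$init
    if (is.null(theta)) {
      theta <- if (length(x) > 0) moment_init(x)
      else c(stats::runif(1), abs(stats::rnorm(1, 0, sigma_r)), stats::runif(1))
    }
    stopifnot(length(theta) == 3)
    lp_cur <- log_prior_theta(theta, sigma_r)
    if (!is.finite(lp_cur)) stop("initial state outside the prior support")
    lp_cur <- lp_cur + loglik(theta)
    n_accept <- 0L
    kept <- 0L
    for (i in seq_len(settings$n_samples)) {
      sd_cur <- pmax(scale * theta, floor_sd)
      prop <- stats::rnorm(3, theta, sd_cur)
      lp_prop <- log_prior_theta(prop, sigma_r)
      if (is.finite(lp_prop)) {
        lp_prop <- lp_prop + loglik(prop)
        log_ratio <- lp_prop - lp_cur
        if (hastings) {
          sd_prop <- pmax(scale * prop, floor_sd)
          log_ratio <- log_ratio +
            sum(stats::dnorm(theta, prop, sd_prop, log = TRUE)) -
            sum(stats::dnorm(prop, theta, sd_cur, log = TRUE))
        }
        if (is.finite(log_ratio) && log(stats::runif(1)) < log_ratio) {
          theta <- prop
          lp_cur <- lp_prop
          n_accept <- n_accept + 1L
        }
      }
      if (i > settings$burn_in && (i - settings$burn_in) %% settings$thin == 0L) {
        kept <- kept + 1L
        samples[kept, ] <- theta
        lps[kept] <- lp_cur
      }
    }
    list(n_accept = n_accept, kept = kept)
  })

  acc <- res$n_accept / settings$n_samples
  warns <- character(0)
  if (acc < 0.01) warns <- c(warns, "acceptance rate below 1%: chain likely stuck")
  if (acc > 0.99) warns <- c(warns, "acceptance rate above 99%: steps likely too small")
  for (w in warns) warning(w, call. = FALSE)

  structure(list(samples = samples[seq_len(res$kept), , drop = FALSE],
                 log_posteriors = lps[seq_len(res$kept)],
                 acceptance_rate = acc, settings = settings,
                 data_digest = digest_counts(x), warnings = warns),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("Posterior chain:", nrow(x$samples), "retained samples",
      sprintf("(acceptance %.1f%%)\n", 100 * x$acceptance_rate))
  print(round(apply(x$samples, 2, stats::quantile,
                    probs = c(0.025, 0.5, 0.975)), 4))
  invisible(x)
}

digest_counts <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(as.integer(x), NULL), f)
  unname(tools::md5sum(f))
}

#' Maximum a posteriori estimate from a chain
#'
#' The retained sample with the largest log posterior (no density
#' smoothing, so the estimate is exactly reproducible).
#'
#' @param chain A `posterior_chain` from [run_mcmc()].
#' @return A [zinb_params()] object.
#' @export
map_estimate <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"), nrow(chain$samples) >= 1)
  i <- which.max(chain$log_posteriors)
  zinb_params(unname(chain$samples[i, "omega"]),
              unname(chain$samples[i, "r"]),
              unname(chain$samples[i, "p"]))
}

#' Equal-tailed credible intervals
#'
#' @param chain A `posterior_chain`.
#' @param level Credible level (default 0.95).
#' @return A matrix with rows `omega`, `r`, `p` and columns `low`, `high`.
#' @export
credible_intervals <- function(chain, level = 0.95) {
  stopifnot(inherits(chain, "posterior_chain"), level >= 0, level <= 1)
  if (nrow(chain$samples) < 100 && level > 0)
    warning("fewer than 100 retained samples; intervals are unstable",
            call. = FALSE)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(chain$samples, 2, stats::quantile, probs = probs,
                names = FALSE))
  dimnames(ci) <- list(c("omega", "r", "p"), c("low", "high"))
  ci
}

#' Fit one condition end to end
#'
#' Applies the artifact filter, runs the sampler, and reports the MAP
#' estimate with 95% credible intervals for the statistical parameters and
#' for the derived burst kinetics (each retained sample is transformed via
#' [statistical_to_kinetics()] before taking quantiles).
#'
#' @param counts A single-condition [count_dataset()] or integer vector.
#' @param settings An [mcmc_settings()] object.
#' @param max_count Artifact filter threshold (default 150).
#' @param level Credible level.
#' @return A list of class `burst_fit`: `map` ([zinb_params()]),
#'   `intervals`, `kinetics_map` ([burst_kinetics()]),
#'   `kinetics_intervals`, `n_cells_used`, `n_cells_filtered`, `chain`,
#'   `diagnostics` (from [convergence_report()]).
#' @export
fit_condition <- function(counts, settings = mcmc_settings(),
                          max_count = 150, level = 0.95) {
  x <- count_vector(counts)
  n0 <- length(x)
  x <- x[x <= max_count]
  if (length(x) == 0) stop("no cells left after filtering", call. = FALSE)
  chain <- run_mcmc(x, settings)
  map <- map_estimate(chain)
  ci <- credible_intervals(chain, level)
  freq <- chain$samples[, "r"]
  size <- chain$samples[, "p"] / (1 - chain$samples[, "p"])
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  kin_ci <- rbind(burst_frequency = stats::quantile(freq, probs, names = FALSE),
                  burst_size = stats::quantile(size, probs, names = FALSE),
                  omega = ci["omega", ])
  colnames(kin_ci) <- c("low", "high")
  structure(list(map = map, intervals = ci,
                 kinetics_map = statistical_to_kinetics(map),
                 kinetics_intervals = kin_ci,
                 n_cells_used = length(x), n_cells_filtered = n0 - length(x),
                 chain = chain,
                 diagnostics = convergence_report(chain, quiet = TRUE)),
            class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat("Burst-kinetics fit (", x$n_cells_used, " cells used, ",
      x$n_cells_filtered, " filtered)\n", sep = "")
  cat(sprintf("  omega  MAP %.4f  [%.4f, %.4f]\n", x$map$omega,
              x$intervals["omega", 1], x$intervals["omega", 2]))
  cat(sprintf("  burst frequency  MAP %.4f  [%.4f, %.4f]\n",
              x$kinetics_map$burst_frequency,
              x$kinetics_intervals["burst_frequency", 1],
              x$kinetics_intervals["burst_frequency", 2]))
  cat(sprintf("  burst size  MAP %.4f  [%.4f, %.4f]\n",
              x$kinetics_map$burst_size,
              x$kinetics_intervals["burst_size", 1],
              x$kinetics_intervals["burst_size", 2]))
  invisible(x)
}

# effective sample size from the truncated autocorrelation sum
# (pairwise-positive truncation in the style of Geyer's initial sequence)
ess_acf <- function(v) {
  n <- length(v)
  if (stats::var(v) == 0) return(1)
  rho <- stats::acf(v, lag.max = min(n - 1, 1000), plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  k <- 1
  while (k <= length(rho)) {
    pair <- rho[k] + if (k + 1 <= length(rho)) rho[k + 1] else 0
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n / (1 + 2 * s))
}

split_rhat <- function(v) {
  n <- length(v) %/% 2
  a <- v[seq_len(n)]
  b <- v[seq.int(length(v) - n + 1, length(v))]
  W <- (stats::var(a) + stats::var(b)) / 2
  if (W == 0) return(1)
  B <- n * stats::var(c(mean(a), mean(b)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for a posterior chain
#'
#' Reports the acceptance rate, a per-parameter effective sample size from
#' the truncated autocorrelation sum, and a split-chain comparison
#' statistic (potential scale reduction computed between the two halves of
#' the retained chain).  Flags are raised when ESS < 100 or split-Rhat >
#' 1.05.
#'
#' @param chain A `posterior_chain` with at least 200 retained samples.
#' @param quiet Suppress the flag messages.
#' @return A list: `acceptance_rate`, `ess` (named vector), `split_rhat`
#'   (named vector), `flags` (character vector, possibly empty).
#' @export
convergence_report <- function(chain, quiet = FALSE) {
  stopifnot(inherits(chain, "posterior_chain"))
  s <- chain$samples
  if (nrow(s) < 200 && !quiet)
    warning("fewer than 200 retained samples; diagnostics are unreliable",
            call. = FALSE)
  ess <- apply(s, 2, ess_acf)
  rhat <- apply(s, 2, split_rhat)
  flags <- character(0)
  for (pn in colnames(s)) {
    if (ess[pn] < 100)
      flags <- c(flags, sprintf("ESS(%s) = %.0f < 100", pn, ess[pn]))
    if (rhat[pn] > 1.05)
      flags <- c(flags, sprintf("split-Rhat(%s) = %.3f > 1.05", pn, rhat[pn]))
  }
  if (!quiet) for (f in flags) message("convergence flag: ", f)
  list(acceptance_rate = chain$acceptance_rate, ess = ess,
       split_rhat = rhat, flags = flags)
}

#' Resume a chain from its last state
#'
#' Continues sampling from the final retained state of an existing chain
#' and appends the new retained samples (the restart strategy used when a
#' chain has not yet converged).
#'
#' @param chain A `posterior_chain`.
#' @param counts The same counts the chain was built from.
#' @param n_samples Additional iterations (no extra burn-in is discarded).
#' @param seed Seed for the continuation.
#' @return A `posterior_chain` with the appended samples.
#' @export
resume_mcmc <- function(chain, counts, n_samples, seed) {
  stopifnot(inherits(chain, "posterior_chain"), nrow(chain$samples) >= 1)
  last <- chain$samples[nrow(chain$samples), ]
  s <- chain$settings
  s2 <- mcmc_settings(n_samples = n_samples, burn_in = 0, thin = s$thin,
                      proposal_scale = s$proposal_scale,
                      proposal_floor = s$proposal_floor, seed = seed,
                      prior_r_sigma = s$prior_r_sigma,
                      hastings_correction = s$hastings_correction,
                      init = as.numeric(last))
  more <- run_mcmc(counts, s2)
  structure(list(samples = rbind(chain$samples, more$samples),
                 log_posteriors = c(chain$log_posteriors, more$log_posteriors),
                 acceptance_rate = more$acceptance_rate,
                 settings = chain$settings, data_digest = more$data_digest,
                 warnings = c(chain$warnings, more$warnings)),
            class = "posterior_chain")
}
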