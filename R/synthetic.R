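# Synthetic single-cell count data with the statistical structure the
# analysis assumes: direct ZINB sampling, exact Gillespie simulation of the
# three-state promoter, multi-condition scenarios and artifact injection.

# All samplers take an explicit seed and restore the caller's RNG state, so
# nothing in the package leaks global randomness.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Sample i.i.d. cells from the zero-inflated negative binomial
#'
#' Each cell is silent (count 0) with probability `omega`, otherwise its
#' count is drawn from the negative binomial with shape `r` and success
#' parameter `p` (mean `r * p / (1-p)`).
#'
#' @param params A [zinb_params()] object.
#' @param n_cells Number of cells to draw.
#' @param seed Integer seed; the draw is reproducible and the caller's RNG
#'   state is untouched.
#' @param condition Condition label stored with the cells.
#' @return A [count_dataset()].
#' @examples
#' d <- sample_zinb(zinb_params(0.3, 2, 0.9), n_cells = 500, seed = 1)
#' mean(d$count)
#' @export
sample_zinb <- function(params, n_cells, seed, condition = "sim") {
  stopifnot(inherits(params, "zinb_params"), n_cells >= 1)
  counts <- local_seed(seed, {
    inflated <- stats::runif(n_cells) < params$omega
    x <- stats::rnbinom(n_cells, size = params$r, prob = 1 - params$p)
    x[inflated] <- 0L
    x
  })
  count_dataset(cell_id = sprintf("cell_%06d", seq_len(n_cells)),
                condition = condition, count = counts,
                provenance = list(generator = "sample_zinb", seed = seed,
                                  params = unclass(params)))
}

#' Exact stochastic simulation of the three-state promoter
#'
#' Direct-method Gillespie simulation of the continuous-time Markov chain
#' with reactions C->B (`alpha`), B->C (`beta`), B->A (`lambda`), A->B
#' (`nu`), transcription in A (`K`) and first-order mRNA decay (`n * delta`).
#' The event sequence is statistically exact; the trajectory stops at the
#' first event whose time would exceed `t_end`.
#'
#' @param rates A [burst_model_params()] object.
#' @param t_end Simulation horizon, in units of `1/delta`.
#' @param initial_state One of `"C"`, `"B"`, `"A"`.
#' @param initial_mrna Starting mRNA copy number.
#' @param seed Integer seed.
#' @param max_events Safety cap on the number of events.
#' @return A list of class `ssa_trajectory` with components `times`
#'   (event times, starting at 0), `states` (promoter state letters) and
#'   `mrna` (copy number after each event).
#' @examples
#' tr <- simulate_ssa(burst_model_params(0.1, 0.1, 2, 10, 50), t_end = 20,
#'                    seed = 1)
#' tail(tr$mrna)
#' @export
simulate_ssa <- function(rates, t_end, initial_state = "C", initial_mrna = 0,
                         seed, max_events = 1e8) {
  stopifnot(inherits(rates, "burst_model_params"), t_end > 0,
            initial_mrna >= 0, initial_mrna == floor(initial_mrna))
  state0 <- match(match.arg(initial_state, c("C", "B", "A")), c("C", "B", "A")) - 1L
  res <- local_seed(seed, ssa_trajectory_cpp(
    rates$alpha, rates$beta, rates$lambda, rates$nu, rates$K, rates$delta,
    t_end, state0, as.integer(initial_mrna), max_events))
  structure(list(times = res$times,
                 states = c("C", "B", "A")[res$states + 1L],
                 mrna = res$mrna, rates = rates, t_end = t_end, seed = seed),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("SSA trajectory:", length(x$times) - 1L, "events over t in [0,",
      format(x$t_end), "]; final state", x$states[length(x$states)],
      "with", x$mrna[length(x$mrna)], "mRNAs\n")
  invisible(x)
}

#' Stationary promoter-state distribution of the three-state chain
#'
#' The chain C <-> B <-> A is a birth-death chain, so the stationary
#' probabilities follow from detailed balance; degenerate rates (an
#' unreachable or absorbing end state) are handled by solving the rate
#' matrix null space.
#'
#' @param rates A [burst_model_params()] object.
#' @return Named probability vector over `c("C", "B", "A")`.
#' @export
stationary_promoter_dist <- function(rates) {
  stopifnot(inherits(rates, "burst_model_params"))
  Q <- matrix(0, 3, 3, dimnames = list(c("C", "B", "A"), c("C", "B", "A")))
  Q["C", "B"] <- rates$alpha; Q["B", "C"] <- rates$beta
  Q["B", "A"] <- rates$lambda; Q["A", "B"] <- rates$nu
  diag(Q) <- -rowSums(Q)
  # left null vector of Q: pi Q = 0, sum(pi) = 1
  A <- rbind(t(Q), rep(1, 3))
  pi_hat <- tryCatch(stats::setNames(qr.solve(A, c(0, 0, 0, 1)), c("C", "B", "A")),
                     error = function(e) stop(
                       "stationary promoter distribution is not unique for these rates",
                       call. = FALSE))
  if (any(pi_hat < -1e-10))
    stop("stationary promoter distribution is not unique for these rates",
         call. = FALSE)
  pmax(pi_hat, 0) / sum(pmax(pi_hat, 0))
}

#' Population snapshot from independent promoter trajectories
#'
#' Simulates `n_cells` independent cells, each started from the stationary
#' promoter-state distribution with zero mRNAs and run for `t_relax`, and
#' records the terminal (state, count) pair — the single-timepoint snapshot
#' an smFISH experiment measures.
#'
#' @param rates A [burst_model_params()] object.
#' @param n_cells Number of cells.
#' @param t_relax Relaxation horizon; the default `20 * max(1/delta,
#'   1/(alpha+beta))` covers the slow deep-inactive exchange mode.
#' @param seed Integer seed.
#' @param condition Condition label.
#' @param max_events Safety cap per cell.
#' @return A list with elements `data` (a [count_dataset()]) and
#'   `state_fractions` (empirical occupancy of C, B, A at sampling time).
#' @examples
#' r <- burst_model_params(1, 3, 2, 10, 90)
#' pop <- sample_population_ssa(r, n_cells = 200, seed = 1)
#' pop$state_fractions
#' @export
sample_population_ssa <- function(rates, n_cells,
                                  t_relax = 20 * max(1 / rates$delta,
                                                     1 / (rates$alpha + rates$beta)),
                                  seed, condition = "ssa",
                                  max_events = 1e8) {
  stopifnot(inherits(rates, "burst_model_params"), n_cells >= 1, t_relax > 0)
  pi_hat <- stationary_promoter_dist(rates)
  res <- local_seed(seed, {
    init <- sample.int(3L, n_cells, replace = TRUE, prob = pi_hat) - 1L
    ssa_population_cpp(rates$alpha, rates$beta, rates$lambda, rates$nu,
                       rates$K, rates$delta, t_relax, init, max_events)
  })
  fr <- tabulate(res$states + 1L, nbins = 3L) / n_cells
  names(fr) <- c("C", "B", "A")
  data <- count_dataset(cell_id = sprintf("cell_%06d", seq_len(n_cells)),
                        condition = condition, count = res$counts,
                        provenance = list(generator = "sample_population_ssa",
                                          seed = seed, t_relax = t_relax,
                                          rates = unclass(rates)))
  list(data = data, state_fractions = fr)
}

#' Inject artifact high-count cells
#'
#' smFISH images occasionally yield cells with several hundred apparent
#' mRNAs from probe aggregation or non-specific hybridisation.  This helper
#' replaces a Bernoulli subset of counts with uniform draws from a
#' high-count range so that downstream filtering (counts above 150 removed)
#' can be exercised; the affected cells are recorded in the provenance.
#'
#' @param data A [count_dataset()].
#' @param fraction Probability that each cell becomes an artifact, in `[0, 1)`.
#' @param count_range Integer interval `c(lo, hi)` of artifact counts;
#'   `lo` must exceed 150 so the standard filter removes every artifact.
#' @param seed Integer seed.
#' @return A [count_dataset()] whose provenance gains an `artifact_cells`
#'   element (cell_ids that were replaced).
#' @export
inject_artifact_cells <- function(data, fraction, count_range, seed) {
  stopifnot(is_count_dataset(data), fraction >= 0, fraction < 1,
            length(count_range) == 2L, count_range[1] <= count_range[2])
  if (count_range[1] <= 150)
    stop("count_range lower bound must exceed 150 so the standard filter ",
         "removes the artifacts", call. = FALSE)
  if (fraction == 0) {
    prov <- c(provenance(data), list(artifact_cells = character(0)))
    attr(data, "provenance") <- prov
    return(data)
  }
  out <- local_seed(seed, {
    hit <- stats::runif(nrow(data)) < fraction
    counts <- data$count
    counts[hit] <- as.integer(floor(stats::runif(sum(hit), count_range[1],
                                                 count_range[2] + 1)))
    list(counts = counts, hit = hit)
  })
  prov <- c(provenance(data),
            list(artifact_cells = data$cell_id[out$hit],
                 artifact_seed = seed, artifact_range = count_range))
  count_dataset(data$cell_id, data$condition, out$counts, provenance = prov)
}

#' Generate a multi-condition synthetic scenario
#'
#' Builds one dataset containing several conditions, each sampled either
#' directly from a zero-inflated negative binomial ([sample_zinb()]) or
#' mechanistically from the three-state promoter model
#' ([sample_population_ssa()]), depending on the class of the parameters
#' supplied.  Per-condition seeds are derived deterministically from `seed`.
#'
#' @param spec A list of condition specs, each a list with elements
#'   `condition` (unique label), `params` (a [zinb_params()] or
#'   [burst_model_params()]) and `n_cells`.
#' @param seed Integer master seed.
#' @return A [count_dataset()] with one block per condition.
#' @examples
#' sc <- generate_scenario(list(
#'   list(condition = "low", params = zinb_params(0.3, 0.2, 0.9), n_cells = 100),
#'   list(condition = "high", params = zinb_params(0.3, 2.0, 0.9), n_cells = 100)),
#'   seed = 7)
#' table(sc$condition)
#' @export
generate_scenario <- function(spec, seed) {
  stopifnot(is.list(spec), length(spec) >= 1)
  labels <- vapply(spec, function(s) s$condition, "")
  if (anyDuplicated(labels))
    stop("condition labels must be unique", call. = FALSE)
  parts <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    cond_seed <- derive_seed(seed, s$condition)
    if (inherits(s$params, "zinb_params")) {
      parts[[i]] <- sample_zinb(s$params, s$n_cells, seed = cond_seed,
                                condition = s$condition)
    } else if (inherits(s$params, "burst_model_params")) {
      parts[[i]] <- sample_population_ssa(s$params, s$n_cells,
                                          seed = cond_seed,
                                          condition = s$condition)$data
    } else {
      stop("params for condition '", s$condition,
           "' must be zinb_params or burst_model_params", call. = FALSE)
    }
  }
  df <- do.call(rbind, lapply(parts, as.data.frame))
  count_dataset(df$cell_id, df$condition, df$count,
                provenance = list(generator = "generate_scenario", seed = seed,
                                  conditions = labels,
                                  parts = lapply(parts, provenance)))
}

# Deterministic per-stage seed: mixes the master seed with a label hash,
# keeping the result inside the 32-bit range set.seed accepts.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}
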