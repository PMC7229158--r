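# Synthetic-data generators: direct ZINB sampling, exact SSA, population
# snapshots, artifact injection, multi-condition scenarios.

test_that("ZINB sampler matches its distribution and is reproducible", {
  # full inflation: every cell silent
  expect_true(all(sample_zinb(zinb_params(1, 2, 0.5), 100, seed = 1)$count == 0))

  pp <- zinb_params(0.3, 2, 0.9)
  d <- sample_zinb(pp, 1e4, seed = 2)
  m <- zinb_moments(pp)
  se <- sqrt(m$variance / 1e4)
  expect_lt(abs(mean(d$count) - m$mean), 4 * se)

  expect_identical(sample_zinb(pp, 50, seed = 7)$count,
                   sample_zinb(pp, 50, seed = 7)$count)
  expect_false(identical(sample_zinb(pp, 50, seed = 7)$count,
                         sample_zinb(pp, 50, seed = 8)$count))
  # no global RNG leakage
  withr::with_seed(99, {
    before <- runif(1)
  })
  withr::with_seed(99, {
    invisible(sample_zinb(pp, 10, seed = 3))
    expect_equal(runif(1), before)
  })
})

test_that("SSA degenerate cases behave as the reactions dictate", {
  # no transcription: mRNA stays at zero
  tr <- simulate_ssa(burst_model_params(1, 1, 2, 10, 0), t_end = 20,
                     initial_state = "B", seed = 1)
  expect_true(all(tr$mrna == 0))
  # absorbing deep-inactive state: no events at all
  tr <- simulate_ssa(burst_model_params(0, 0, 2, 10, 50), t_end = 20,
                     initial_state = "C", seed = 1)
  expect_length(tr$times, 1L)
  expect_equal(tr$states, "C")
})

test_that("two-state limit reproduces the telegraph mean", {
  # beta = 0, start in B: C unreachable, classic telegraph promoter
  lambda <- 2; nu <- 10; K <- 50
  rates <- burst_model_params(0, 0, lambda, nu, K, delta = 1)
  avg <- vapply(1:200, function(i) {
    tr <- simulate_ssa(rates, t_end = 500, initial_state = "B", seed = 5000 + i)
    trajectory_time_average(tr, t_from = 20)
  }, 0)
  theory <- K * lambda / (lambda + nu)
  se <- sd(avg) / sqrt(length(avg))
  expect_lt(abs(mean(avg) - theory), 3 * se)
})

test_that("SSA matches the Poisson immigration-death law", {
  # locked in the active state (alpha = beta = 0 from A, nu = 0): counts at
  # time t are Poisson with mean (K/delta)(1 - exp(-delta t))
  K <- 20; t_snap <- 5
  rates <- burst_model_params(0, 0, 0, 0, K, delta = 1)
  finals <- vapply(1:500, function(i) {
    tr <- simulate_ssa(rates, t_end = t_snap, initial_state = "A", seed = 300 + i)
    tr$mrna[length(tr$mrna)]
  }, 0L)
  lam <- K * (1 - exp(-t_snap))
  se_mean <- sd(finals) / sqrt(500)
  expect_lt(abs(mean(finals) - lam), 3 * se_mean)
  # variance of a Poisson equals its mean; SE of the sample variance from
  # the fourth central moment
  v <- var(finals)
  m4 <- mean((finals - mean(finals))^4)
  se_var <- sqrt((m4 - v^2) / 500)
  expect_lt(abs(v - lam), 3 * se_var)
})

test_that("long-trajectory promoter occupancy matches the stationary chain", {
  rates <- burst_model_params(1, 3, 2, 10, 20)
  tr <- simulate_ssa(rates, t_end = 1e4, initial_state = "B", seed = 11)
  occ <- trajectory_state_occupancy(tr)
  expect_lt(max(abs(occ - stationary_promoter_dist(rates))), 0.01)
})

test_that("population snapshots have the stationary deep-state fraction", {
  # bursty regime: nu >> lambda, so the C fraction is close to beta/(alpha+beta)
  rates <- burst_model_params(1, 3, 2, 50, 90)
  pop <- sample_population_ssa(rates, n_cells = 1e4, seed = 21)
  expect_lt(abs(pop$state_fractions["C"] - 0.75), 4 * sqrt(0.75 * 0.25 / 1e4))
  expect_equal(sum(pop$state_fractions), 1)
  # beta = 0 with a reachable B: the deep state empties
  rates0 <- burst_model_params(1, 0, 2, 10, 20)
  pop0 <- sample_population_ssa(rates0, n_cells = 500, seed = 22)
  expect_equal(unname(pop0$state_fractions["C"]), 0)
})

test_that("artifact injection is Bernoulli, recorded, and filterable", {
  clean <- sample_zinb(zinb_params(0.3, 2, 0.7), 1e4, seed = 31)
  expect_true(all(clean$count <= 150))  # small burst size: no real tail

  same <- inject_artifact_cells(clean, fraction = 0, count_range = c(300, 600),
                                seed = 32)
  expect_identical(same$count, clean$count)

  art <- inject_artifact_cells(clean, fraction = 0.05,
                               count_range = c(300, 600), seed = 33)
  hit <- provenance(art)$artifact_cells
  expect_lt(abs(length(hit) - 500), 4 * sqrt(1e4 * 0.05 * 0.95))
  expect_true(all(art$count[art$cell_id %in% hit] >= 300))
  expect_true(all(art$count[art$cell_id %in% hit] <= 600))

  flt <- filter_counts(art, 150)
  expect_equal(flt$n_removed, length(hit))
  expect_setequal(setdiff(art$cell_id, flt$data$cell_id), hit)

  expect_error(inject_artifact_cells(clean, 0.05, c(100, 600), seed = 1),
               "150")
})

test_that("scenario generation concatenates reproducible condition blocks", {
  pp <- zinb_params(0.3, 2, 0.9)
  one <- generate_scenario(list(list(condition = "a", params = pp,
                                     n_cells = 200)), seed = 41)
  expect_equal(sort(unique(one$condition)), "a")
  expect_equal(nrow(one), 200)

  expect_error(generate_scenario(list(
    list(condition = "a", params = pp, n_cells = 10),
    list(condition = "a", params = pp, n_cells = 10)), seed = 1), "unique")

  # frequency-regulated pair (shared burst size 11.3): higher frequency
  # gives higher mean, lower noise
  freq_pair <- generate_scenario(list(
    list(condition = "low_freq", params = zinb_params(0.3, 0.2, 11.3 / 12.3),
         n_cells = 5000),
    list(condition = "high_freq", params = zinb_params(0.3, 2.0, 11.3 / 12.3),
         n_cells = 5000)), seed = 42)
  s <- summarize_counts(freq_pair, n_boot = 0)
  expect_gt(s$mu[s$condition == "high_freq"], s$mu[s$condition == "low_freq"])
  expect_lt(s$cv2[s$condition == "high_freq"], s$cv2[s$condition == "low_freq"])

  # size-regulated pair (shared frequency 1.89): bigger bursts, bigger Fano
  size_pair <- generate_scenario(list(
    list(condition = "small_burst", params = zinb_params(0.3, 1.89, 0.5 / 1.5),
         n_cells = 5000),
    list(condition = "big_burst", params = zinb_params(0.3, 1.89, 10 / 11),
         n_cells = 5000)), seed = 43)
  s2 <- summarize_counts(size_pair, n_boot = 0)
  expect_gt(s2$fano[s2$condition == "big_burst"],
            s2$fano[s2$condition == "small_burst"])

  # deterministic given the master seed
  again <- generate_scenario(list(
    list(condition = "low_freq", params = zinb_params(0.3, 0.2, 11.3 / 12.3),
         n_cells = 5000),
    list(condition = "high_freq", params = zinb_params(0.3, 2.0, 11.3 / 12.3),
         n_cells = 5000)), seed = 42)
  expect_identical(again$count, freq_pair$count)

  # SSA-backed condition blocks work through the same interface
  mech <- generate_scenario(list(
    list(condition = "mech", params = burst_model_params(1, 3, 2, 10, 90),
         n_cells = 300)), seed = 44)
  expect_equal(nrow(mech), 300)
})
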