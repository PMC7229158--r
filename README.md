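# burstfit

Transcriptional burst kinetics from single-cell mRNA counts.

## What problem this solves

Single-molecule RNA FISH gives absolute mRNA copy numbers per cell across
a population. Two genes with the same *mean* expression can reach it in
very different ways: frequent small bursts (low cell-to-cell variability)
or rare large bursts (high variability). `burstfit` is for researchers who
have such per-cell count tables and want to (i) quantify noise and
burstiness, (ii) infer the underlying burst kinetics with honest
uncertainty, and (iii) compare the data against the scaling behaviour
expected when regulation acts only on burst size or only on burst
frequency.

The core model is a three-state promoter: a deep inactive state C
exchanging slowly (rates α, β) with a primed inactive state B, which
connects to an active state A (on-rate λ, off-rate ν); transcription
occurs in A at rate K, mRNA decays at rate δ (all rates in units of δ).
Slow C/B exchange makes the steady-state copy-number distribution a
zero-inflated negative binomial

    P(0) = ω + (1−ω)(1−p)^r,   P(n) = (1−ω) C(n+r−1, n) (1−p)^r p^n  (n > 0),

with ω = β/(α+β) the deep-inactive occupancy, r = λ/δ the **burst
frequency**, and p/(1−p) = K/ν the **burst size**. The package provides:

- `zinb_log_pmf`, `zinb_moments`, `mechanistic_to_statistical`,
  `statistical_to_kinetics` — the distribution and the rate↔parameter maps;
- `simulate_ssa`, `sample_population_ssa`, `sample_zinb`,
  `inject_artifact_cells`, `generate_scenario` — exact Gillespie
  simulation and synthetic multi-condition datasets;
- `summarize_counts`, `bootstrap_sem` — noise (CV² = σ²/μ²) and
  burstiness (Fano F = σ²/μ) with bootstrap SEMs, after removing
  artifact cells with more than 150 counts;
- `run_mcmc`, `fit_condition`, `map_estimate`, `credible_intervals`,
  `convergence_report` — Metropolis–Hastings inference of (ω, r, p) and
  the derived kinetics, with MAP estimates and 95% credible intervals;
- `cv2_frequency_regulated`, `fano_size_regulated`, …,
  `make_scaling_curves` — closed-form noise/Fano vs mean curves under
  single-parameter regulation;
- `read_counts`, `write_counts`, `run_pipeline` — tidy CSV I/O and a
  seed-deterministic simulate → summarize → fit → predict pipeline with a
  digest manifest.

## Worked example

Simulate a two-condition experiment that shares a burst size of 10 but
differs in burst frequency and silent-fraction, summarize it, and refit
the induced condition:

```r
library(burstfit)

d <- generate_scenario(list(
  list(condition = "basal",   params = zinb_params(0.6, 0.5, 10/11), n_cells = 1000),
  list(condition = "induced", params = zinb_params(0.2, 2.0, 10/11), n_cells = 1000)),
  seed = 42)

summarize_counts(d, n_boot = 1000, seed = 1)
#>   condition n_cells_used n_cells_filtered     mu     sigma       cv2     fano
#> 1     basal         1000                0  1.674  4.741963 8.0242668 13.43262
#> 2   induced         1000                0 16.129 16.099614 0.9963594 16.07028
#>      sem_mu    sem_cv2 sem_fano degenerate
#> 1 0.1501233 0.93246516 1.854716      FALSE
#> 2 0.4882000 0.06245166 1.046062      FALSE

fit_condition(d[d$condition == "induced", ],
              mcmc_settings(n_samples = 20000, burn_in = 5000, thin = 10, seed = 2))
#> Burst-kinetics fit (1000 cells used, 0 filtered)
#>   omega  MAP 0.1954  [0.1745, 0.2173]
#>   burst frequency  MAP 1.8954  [1.7385, 2.1810]
#>   burst size  MAP 10.6053  [9.1584, 11.7006]
```

Reading the numbers: the induced condition reaches a ten-fold higher mean
(16.1 vs 1.7) with *lower* noise (CV² 1.0 vs 8.0) but essentially
unchanged burstiness (Fano ≈ 13–16 ≫ 1): the signature of regulation by
burst *frequency* at constant burst size. The fit recovers the generating
values (ω = 0.2, frequency 2.0, size 10) inside its 95% credible
intervals.

Mechanistic simulation works through the same interface: pass
`burst_model_params(alpha, beta, lambda, nu, K)` instead of
`zinb_params(...)` in a scenario, and cells are drawn by exact stochastic
simulation of the promoter kinetics instead of from the ZINB.

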