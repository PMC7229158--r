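# Descriptive statistics of per-cell count distributions: mean, SD, noise
# (CV^2 = sigma^2/mu^2), burstiness (Fano = sigma^2/mu), the high-count
# artifact filter, and bootstrap standard errors.

#' Remove artifact high-count cells
#'
#' Cells with more than `max_count` apparent mRNAs are treated as imaging or
#' hybridisation artifacts and dropped before any statistic is computed.
#' The boundary is inclusive: a cell with exactly `max_count` is kept.
#'
#' @param data A [count_dataset()].
#' @param max_count Largest count retained (default 150).
#' @return A list with `data` (the filtered [count_dataset()], original
#'   order preserved) and `n_removed`.
#' @export
filter_counts <- function(data, max_count = 150) {
  stopifnot(is_count_dataset(data), max_count >= 0)
  keep <- data$count <= max_count
  list(data = data[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Noise and burstiness from a mean and standard deviation
#'
#' @param mu Mean count per cell, `> 0`.
#' @param sigma Standard deviation of counts, `>= 0`.
#' @return A named list with `cv2 = sigma^2/mu^2` and `fano = sigma^2/mu`.
#' @examples
#' stats_from_moments(0.07, 0.30)  # Fano ~ 1.29: near-Poisson
#' @export
stats_from_moments <- function(mu, sigma) {
  stopifnot(is.numeric(mu), is.numeric(sigma), length(mu) == length(sigma))
  if (any(mu <= 0)) stop("'mu' must be positive", call. = FALSE)
  if (any(sigma < 0)) stop("'sigma' must be non-negative", call. = FALSE)
  list(cv2 = sigma^2 / mu^2, fano = sigma^2 / mu)
}

#' Per-condition summary statistics with bootstrap standard errors
#'
#' Applies the high-count filter, then for each condition computes the mean,
#' standard deviation, noise (CV^2) and burstiness (Fano factor) of the
#' per-cell counts, with standard errors from bootstrap resampling of cells.
#' Conditions whose filtered mean is zero get `NA` noise statistics and a
#' `degenerate` flag rather than an error, so multi-condition sweeps survive
#' all-silent scenarios.
#'
#' @param data A [count_dataset()].
#' @param max_count Filter threshold passed to [filter_counts()].
#' @param n_boot Bootstrap resamples for the SEMs (default 10000); set to 0
#'   to skip the bootstrap.
#' @param seed Seed for the bootstrap.
#' @param sd_type `"sample"` (denominator M-1, default) or `"population"`
#'   (denominator M).
#' @return A data.frame with one row per condition: `condition`,
#'   `n_cells_used`, `n_cells_filtered`, `mu`, `sigma`, `cv2`, `fano`,
#'   `sem_mu`, `sem_cv2`, `sem_fano`, `degenerate`.
#' @examples
#' d <- sample_zinb(zinb_params(0.3, 2, 0.9), 1000, seed = 1)
#' summarize_counts(d, n_boot = 200, seed = 2)
#' @export
summarize_counts <- function(data, max_count = 150, n_boot = 10000, seed = 1,
                             sd_type = c("sample", "population")) {
  stopifnot(is_count_dataset(data))
  sd_type <- match.arg(sd_type)
  flt <- filter_counts(data, max_count)
  conds <- unique(data$condition)
  rows <- lapply(conds, function(cond) {
    x <- flt$data$count[flt$data$condition == cond]
    n_before <- sum(data$condition == cond)
    if (length(x) == 0)
      stop("condition '", cond, "' is empty after filtering", call. = FALSE)
    if (length(x) < 2)
      stop("condition '", cond, "' needs >= 2 cells after filtering",
           call. = FALSE)
    mu <- mean(x)
    s2 <- stats::var(x)
    if (sd_type == "population") s2 <- s2 * (length(x) - 1) / length(x)
    sigma <- sqrt(s2)
    if (mu > 0) {
      st <- stats_from_moments(mu, sigma)
      cv2 <- st$cv2; fano <- st$fano
    } else {
      cv2 <- NA_real_; fano <- NA_real_
    }
    sems <- c(sem_mu = NA_real_, sem_cv2 = NA_real_, sem_fano = NA_real_)
    if (n_boot > 0) {
      bs <- bootstrap_stats(x, n_boot = n_boot,
                            seed = derive_seed(seed, cond), sd_type = sd_type)
      sems <- c(sem_mu = bs$sem["mu"], sem_cv2 = bs$sem["cv2"],
                sem_fano = bs$sem["fano"])
      names(sems) <- c("sem_mu", "sem_cv2", "sem_fano")
    }
    data.frame(condition = cond, n_cells_used = length(x),
               n_cells_filtered = n_before - length(x),
               mu = mu, sigma = sigma, cv2 = cv2, fano = fano,
               sem_mu = sems[["sem_mu"]], sem_cv2 = sems[["sem_cv2"]],
               sem_fano = sems[["sem_fano"]],
               degenerate = mu == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# One bootstrap pass computing mu, cv2 and fano on every resample.
# Resampling is over cells; the artifact filter is applied once upstream and
# not re-applied within resamples.  Resamples on which cv2/fano are
# undefined (mean zero) are dropped from those SDs; if more than 1% are
# dropped a warning is raised and the fraction recorded.
bootstrap_stats <- function(x, n_boot, seed, sd_type = "sample") {
  m <- length(x)
  stat <- matrix(NA_real_, n_boot, 3, dimnames = list(NULL, c("mu", "cv2", "fano")))
  local_seed(seed, {
    for (b in seq_len(n_boot)) {
      xb <- x[sample.int(m, m, replace = TRUE)]
      mu <- mean(xb)
      s2 <- stats::var(xb)
      if (sd_type == "population") s2 <- s2 * (m - 1) / m
      stat[b, "mu"] <- mu
      if (mu > 0) {
        stat[b, "cv2"] <- s2 / mu^2
        stat[b, "fano"] <- s2 / mu
      }
    }
  })
  n_bad <- sum(is.na(stat[, "cv2"]))
  frac_bad <- n_bad / n_boot
  if (frac_bad > 0.01)
    warning(sprintf("cv2/fano undefined on %.1f%% of bootstrap resamples; %s",
                    100 * frac_bad, "they were excluded from the SEMs"),
            call. = FALSE)
  list(sem = apply(stat, 2, stats::sd, na.rm = TRUE),
       frac_undefined = frac_bad)
}

#' Bootstrap standard error of one statistic
#'
#' Standard deviation of a statistic over with-replacement resamples of the
#' cells (each resample the same size as the original sample).
#'
#' @param data A [count_dataset()] (or, for convenience, a numeric count
#'   vector); a single condition is expected.
#' @param statistic One of `"mu"`, `"cv2"`, `"fano"`.
#' @param n_boot Number of resamples (default 10000).
#' @param seed Integer seed.
#' @return The bootstrap SEM (a single non-negative number), with attribute
#'   `frac_undefined` giving the fraction of resamples on which the
#'   statistic was undefined and excluded.
#' @export
bootstrap_sem <- function(data, statistic = c("mu", "cv2", "fano"),
                          n_boot = 10000, seed = 1) {
  statistic <- match.arg(statistic)
  x <- if (is_count_dataset(data)) data$count else as.numeric(data)
  if (length(x) < 2) stop("need at least 2 cells", call. = FALSE)
  bs <- bootstrap_stats(x, n_boot = n_boot, seed = seed)
  structure(unname(bs$sem[statistic]), frac_undefined = bs$frac_undefined)
}
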