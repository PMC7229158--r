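# Closed-form noise/Fano scaling under single-parameter regulation of the
# two-state (telegraph) promoter, with the decay rate delta fixed at 1.
# If only the activation rate lambda varies ("frequency regulation"), the
# burst size K/nu is constant and
#   CV^2(<n>) = 1/<n> + (K - <n>)^2 / (<n> (nu K + K - <n>)),
#   F(<n>)    = 1 + (K - <n>)^2 / (nu K + K - <n>).
# If only the inactivation rate nu varies ("size regulation"), the burst
# frequency lambda is constant and
#   CV^2(<n>) = 1/<n> + (K - <n>) / (lambda K + <n>),
#   F(<n>)    = 1 + <n> (K - <n>) / (lambda K + <n>).
# The mean cannot exceed K (synthesis/decay balance), hence the domain guard.

check_mean_domain <- function(mean, K) {
  if (any(mean <= 0)) stop("mean must be positive", call. = FALSE)
  if (any(mean >= K))
    stop("mean must be below K: the mean cannot exceed the maximal ",
         "synthesis/decay balance", call. = FALSE)
}

#' Noise under burst-frequency regulation
#'
#' Squared coefficient of variation as a function of the mean when only the
#' activation rate (and hence the burst frequency) is regulated; the burst
#' size `K/nu` stays fixed.
#'
#' @param mean Mean mRNA copy number(s), in `(0, K)`.
#' @param K Transcription rate in the active state (units of the decay
#'   rate).
#' @param nu Inactivation rate (units of the decay rate).
#' @return CV^2 values.
#' @export
cv2_frequency_regulated <- function(mean, K, nu) {
  check_mean_domain(mean, K)
  1 / mean + (K - mean)^2 / (mean * (nu * K + K - mean))
}

#' Fano factor under burst-frequency regulation
#' @inheritParams cv2_frequency_regulated
#' @return Fano factor values.
#' @export
fano_frequency_regulated <- function(mean, K, nu) {
  if (any(mean <= 0) || any(mean > K))
    stop("mean must lie in (0, K]", call. = FALSE)
  1 + (K - mean)^2 / (nu * K + K - mean)
}

#' Noise under burst-size regulation
#'
#' CV^2 as a function of the mean when only the inactivation rate (and
#' hence the burst size) is regulated; the burst frequency `lambda` stays
#' fixed.
#'
#' @param mean Mean mRNA copy number(s), in `(0, K)`.
#' @param K Transcription rate in the active state.
#' @param lambda Activation rate (burst frequency, units of the decay
#'   rate).
#' @return CV^2 values.
#' @export
cv2_size_regulated <- function(mean, K, lambda) {
  check_mean_domain(mean, K)
  1 / mean + (K - mean) / (lambda * K + mean)
}

#' Fano factor under burst-size regulation
#' @inheritParams cv2_size_regulated
#' @return Fano factor values.
#' @export
fano_size_regulated <- function(mean, K, lambda) {
  if (any(mean <= 0) || any(mean > K))
    stop("mean must lie in (0, K]", call. = FALSE)
  1 + mean * (K - mean) / (lambda * K + mean)
}

#' Theory curves of noise and Fano factor versus mean expression
#'
#' Evaluates the regime's CV^2 and Fano expressions over a grid of means.
#' Defaults follow the fitted smFISH averages: `K = 1000` with
#' `nu = K/11.3` (constant burst size 11.3) in the frequency-regulated
#' regime, and `lambda = 1.89` (constant burst frequency) in the
#' size-regulated regime; results are not very sensitive to `K`.
#'
#' @param regime `"frequency_regulated"` or `"size_regulated"`.
#' @param K Transcription rate in the active state (default 1000).
#' @param nu Inactivation rate (frequency regime; default `K/11.3`).
#' @param lambda Activation rate (size regime; default 1.89).
#' @param mean_grid Increasing positive means; default 200 log-spaced
#'   points over `[0.01, 0.9 K]`.
#' @return A data.frame of class `scaling_curve` with columns `mean`,
#'   `cv2`, `fano`; the regime and fixed parameters are kept as attributes.
#' @examples
#' sc <- make_scaling_curves("size_regulated")
#' head(sc)
#' @export
make_scaling_curves <- function(regime = c("frequency_regulated",
                                           "size_regulated"),
                                K = 1000, nu = K / 11.3, lambda = 1.89,
                                mean_grid = NULL) {
  regime <- match.arg(regime)
  if (is.null(mean_grid))
    mean_grid <- exp(seq(log(1e-2), log(0.9 * K), length.out = 200))
  if (is.unsorted(mean_grid)) stop("mean_grid must be increasing", call. = FALSE)
  check_mean_domain(mean_grid, K)
  if (regime == "frequency_regulated") {
    cv2 <- cv2_frequency_regulated(mean_grid, K, nu)
    fano <- fano_frequency_regulated(mean_grid, K, nu)
    fixed <- list(K = K, nu = nu)
  } else {
    cv2 <- cv2_size_regulated(mean_grid, K, lambda)
    fano <- fano_size_regulated(mean_grid, K, lambda)
    fixed <- list(K = K, lambda = lambda)
  }
  structure(data.frame(mean = mean_grid, cv2 = cv2, fano = fano),
            regime = regime, fixed_params = fixed,
            class = c("scaling_curve", "data.frame"))
}

#' Sensitivity of the theory curves to K
#'
#' Recomputes a scaling curve over several values of `K`, holding the
#' regulated regime's fixed ratio (burst size `K/nu` or frequency
#' `lambda`) constant.
#'
#' @inheritParams make_scaling_curves
#' @param K_values Values of `K` to sweep.
#' @param burst_size Constant burst size used to set `nu = K/burst_size`
#'   in the frequency regime.
#' @return A data.frame with columns `K`, `mean`, `cv2`, `fano`.
#' @export
sweep_K_sensitivity <- function(regime = c("frequency_regulated",
                                           "size_regulated"),
                                K_values = c(500, 1000, 2000),
                                burst_size = 11.3, lambda = 1.89,
                                mean_grid = NULL) {
  regime <- match.arg(regime)
  out <- lapply(K_values, function(K) {
    sc <- make_scaling_curves(regime, K = K, nu = K / burst_size,
                              lambda = lambda, mean_grid = mean_grid)
    cbind(K = K, as.data.frame(sc))
  })
  do.call(rbind, out)
}
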