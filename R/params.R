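#' Statistical parameters of the zero-inflated negative binomial
#'
#' Constructs and validates the parameter triple of the steady-state mRNA
#' copy-number distribution: a point mass at zero with weight `omega`
#' (the fraction of cells in the deep inactive promoter state) mixed with a
#' negative binomial with shape `r` (burst frequency in units of the mRNA
#' decay rate) and success parameter `p` (so mean burst size is `p/(1-p)`).
#'
#' @param omega Zero-inflation weight, in `[0, 1]`.
#' @param r Negative-binomial shape, `> 0`. Equals the burst frequency
#'   `lambda/delta` under the mechanistic mapping.
#' @param p Negative-binomial success parameter, in `(0, 1)`.
#' @return An object of class `zinb_params`.
#' @seealso [mechanistic_to_statistical()], [statistical_to_kinetics()],
#'   [zinb_log_pmf()]
#' @examples
#' zinb_params(omega = 0.3, r = 2, p = 0.9)
#' @export
zinb_params <- function(omega, r, p) {
  stopifnot(is.numeric(omega), length(omega) == 1L,
            is.numeric(r), length(r) == 1L,
            is.numeric(p), length(p) == 1L)
  if (is.na(omega) || omega < 0 || omega > 1)
    stop("'omega' must lie in [0, 1], got ", omega, call. = FALSE)
  if (is.na(r) || r <= 0)
    stop("'r' must be positive, got ", r, call. = FALSE)
  if (is.na(p) || p <= 0 || p >= 1)
    stop("'p' must lie in (0, 1), got ", p, call. = FALSE)
  structure(list(omega = omega, r = r, p = p), class = "zinb_params")
}

#' @export
print.zinb_params <- function(x, ...) {
  cat("ZINB parameters: omega =", format(x$omega), " r =", format(x$r),
      " p =", format(x$p), "\n")
  invisible(x)
}

#' Mechanistic rates of the three-state promoter model
#'
#' The promoter switches between a deep inactive state C, a primed inactive
#' state B and an active state A; transcription occurs only in A.  All rates
#' are expressed in units of the mRNA decay rate `delta`, which defaults to 1
#' but is retained explicitly so simulated time stays interpretable.
#'
#' Reactions: C -> B at `alpha`, B -> C at `beta`, B -> A at `lambda`,
#' A -> B at `nu`, transcription in A at `K`, decay of each mRNA at `delta`.
#'
#' @param alpha C -> B switching rate (units of `delta`).
#' @param beta B -> C switching rate (units of `delta`).
#' @param lambda B -> A activation rate (units of `delta`).
#' @param nu A -> B inactivation rate (units of `delta`).
#' @param K Transcription rate in the active state (units of `delta`).
#' @param delta mRNA decay rate; the time unit (default 1).
#' @return An object of class `burst_model_params`.
#' @examples
#' burst_model_params(alpha = 1, beta = 3, lambda = 2, nu = 10, K = 90)
#' @export
burst_model_params <- function(alpha, beta, lambda, nu, K, delta = 1) {
  vals <- c(alpha = alpha, beta = beta, lambda = lambda, nu = nu,
            K = K, delta = delta)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rates must be finite and non-negative", call. = FALSE)
  if (delta <= 0)
    stop("'delta' must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, lambda = lambda, nu = nu,
                 K = K, delta = delta),
            class = "burst_model_params")
}

#' @export
print.burst_model_params <- function(x, ...) {
  cat("Three-state promoter rates (units of delta):\n")
  cat("  C->B alpha =", format(x$alpha), "  B->C beta =", format(x$beta), "\n")
  cat("  B->A lambda =", format(x$lambda), "  A->B nu =", format(x$nu), "\n")
  cat("  transcription K =", format(x$K), "  decay delta =", format(x$delta), "\n")
  invisible(x)
}

#' Burst kinetics summary
#'
#' @param burst_frequency Mean number of bursts per mRNA lifetime (`lambda/delta`).
#' @param burst_size Mean number of mRNAs per burst (`K/nu`).
#' @param omega Deep-inactive occupancy.
#' @return An object of class `burst_kinetics`.
#' @export
burst_kinetics <- function(burst_frequency, burst_size, omega) {
  stopifnot(burst_frequency >= 0, burst_size >= 0, omega >= 0, omega <= 1)
  structure(list(burst_frequency = burst_frequency,
                 burst_size = burst_size, omega = omega),
            class = "burst_kinetics")
}

#' @export
print.burst_kinetics <- function(x, ...) {
  cat("Burst kinetics: frequency =", format(x$burst_frequency),
      " size =", format(x$burst_size), " omega =", format(x$omega), "\n")
  invisible(x)
}

#' Map mechanistic promoter rates to the statistical parameters
#'
#' Under slow C <-> B switching the steady-state count distribution is a
#' zero-inflated negative binomial with `omega = beta/(alpha+beta)`,
#' `r = lambda/delta` and `p = K/(nu+K)`.  The `p` convention is chosen so
#' that the mean burst size equals `p/(1-p) = K/nu` and the model mean is
#' `(1-omega) * (lambda/delta) * (K/nu)`.
#'
#' @param rates A [burst_model_params()] object.
#' @return A [zinb_params()] object.
#' @examples
#' mechanistic_to_statistical(
#'   burst_model_params(alpha = 1, beta = 3, lambda = 2, nu = 10, K = 90))
#' @export
mechanistic_to_statistical <- function(rates) {
  stopifnot(inherits(rates, "burst_model_params"))
  if (rates$alpha + rates$beta <= 0)
    stop("deep-inactive occupancy undefined: alpha + beta must be > 0",
         call. = FALSE)
  if (rates$nu + rates$K <= 0)
    stop("'p' undefined: nu + K must be > 0", call. = FALSE)
  zinb_params(omega = rates$beta / (rates$alpha + rates$beta),
              r = rates$lambda / rates$delta,
              p = rates$K / (rates$nu + rates$K))
}

#' Extract burst kinetics from statistical parameters
#'
#' Burst frequency is `r` (bursts per mRNA lifetime) and burst size is the
#' negative-binomial odds `p/(1-p)`; `omega` is passed through.
#'
#' @param params A [zinb_params()] object.
#' @return A [burst_kinetics()] object.
#' @examples
#' statistical_to_kinetics(zinb_params(0.2, 3, 0.5))
#' @export
statistical_to_kinetics <- function(params) {
  stopifnot(inherits(params, "zinb_params"))
  if (params$p >= 1)
    stop("burst size infinite at p = 1", call. = FALSE)
  burst_kinetics(burst_frequency = params$r,
                 burst_size = params$p / (1 - params$p),
                 omega = params$omega)
}
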