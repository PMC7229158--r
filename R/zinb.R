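#' Log probability mass of the zero-inflated negative binomial
#'
#' Steady-state copy-number distribution of the three-state promoter model:
#' a cell is in the deep inactive state with probability `omega` and then
#' carries zero mRNAs; otherwise counts follow a negative binomial with
#' shape `r` and success parameter `p`,
#' \deqn{P(0) = \omega + (1-\omega)(1-p)^r, \quad
#'       P(n) = (1-\omega)\binom{n+r-1}{n}(1-p)^r p^n \;\; (n > 0).}
#' The generalised binomial coefficient is evaluated through log-gamma so
#' that `r` may be any positive real, and all work is done in log space so
#' counts up to at least 1e4 neither overflow nor underflow.
#'
#' @param params A [zinb_params()] object.
#' @param n Vector of non-negative integer counts.
#' @return Log-probabilities, same length as `n` (`-Inf` where `P(n) = 0`).
#' @examples
#' exp(zinb_log_pmf(zinb_params(0, 1, 0.5), 0:2))  # geometric: 0.5 0.25 0.125
#' @export
zinb_log_pmf <- function(params, n) {
  stopifnot(inherits(params, "zinb_params"))
  if (length(n) == 0L) return(numeric(0))
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n)))
    stop("'n' must contain non-negative integers", call. = FALSE)
  omega <- params$omega; r <- params$r; p <- params$p

  # log NB mass; lchoose-style coefficient via lgamma handles non-integer r
  log_nb <- lgamma(n + r) - lgamma(r) - lgamma(n + 1) +
    r * log1p(-p) + n * log(p)

  out <- numeric(length(n))
  zero <- n == 0
  if (any(zero)) {
    if (omega == 0) {
      out[zero] <- r * log1p(-p)
    } else if (omega == 1) {
      out[zero] <- 0
    } else {
      # log(omega + (1-omega)(1-p)^r) via log-sum-exp
      a <- log(omega)
      b <- log1p(-omega) + r * log1p(-p)
      m <- pmax(a, b)
      out[zero] <- m + log(exp(a - m) + exp(b - m))
    }
  }
  if (any(!zero)) {
    out[!zero] <- if (omega == 1) -Inf else log1p(-omega) + log_nb[!zero]
  }
  out
}

#' Tabulate the zero-inflated negative binomial pmf
#'
#' @param params A [zinb_params()] object.
#' @param n_max Largest count to tabulate (non-negative integer).
#' @return Numeric vector of length `n_max + 1`; element `i` is `P(i - 1)`.
#' @examples
#' zinb_pmf_vector(zinb_params(0, 1, 0.5), 4)
#' @export
zinb_pmf_vector <- function(params, n_max) {
  stopifnot(length(n_max) == 1L, n_max >= 0, n_max == floor(n_max))
  exp(zinb_log_pmf(params, 0:n_max))
}

#' Closed-form mean and variance of the zero-inflated negative binomial
#'
#' With burst size `b = p/(1-p)` the mean is `(1-omega) * r * b` and the
#' variance is `(1-omega) * r * b * (1+b) + omega * (1-omega) * (r*b)^2`
#' (negative-binomial variance plus the between-component term of the
#' zero-inflation mixture).
#'
#' @param params A [zinb_params()] object.
#' @return A named list with elements `mean` and `variance`.
#' @examples
#' zinb_moments(zinb_params(0.3, 2, 0.9))  # mean 12.6
#' @export
zinb_moments <- function(params) {
  stopifnot(inherits(params, "zinb_params"))
  b <- params$p / (1 - params$p)
  m_nb <- params$r * b
  v_nb <- params$r * b * (1 + b)
  w <- params$omega
  list(mean = (1 - w) * m_nb,
       variance = (1 - w) * v_nb + w * (1 - w) * m_nb^2)
}

#' Truncation point covering all but a tiny tail of the distribution
#'
#' Extends the support until the cumulative mass reaches `1 - tail`,
#' used by summation-based checks of the closed-form moments.
#'
#' @param params A [zinb_params()] object.
#' @param tail Maximum mass allowed beyond the returned count.
#' @param cap Hard upper bound on the search (error if reached).
#' @return Smallest `n_max` with cumulative mass `>= 1 - tail`.
#' @keywords internal
#' @export
zinb_support_bound <- function(params, tail = 1e-12, cap = 1e6) {
  n_max <- 64L
  repeat {
    cum <- sum(zinb_pmf_vector(params, n_max))
    if (cum >= 1 - tail) return(n_max)
    if (n_max >= cap)
      stop("support bound search exceeded cap of ", cap, call. = FALSE)
    n_max <- min(as.integer(cap), n_max * 4L)
  }
}
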