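#' Measurement-time density
#'
#' A probability density for the (random, unobserved) time at which a
#' measurement was actually taken, with its cumulative distribution function
#' and a finite support.  The cdf is used directly by the MTU filter whenever
#' it is analytically available; the filter only falls back to Euler
#' accumulation of the pdf when `cdf` is `NULL`.
#'
#' @param pdf Vectorized function `(t)` returning the density (1/h); must be
#'   0 outside `support`.
#' @param cdf Vectorized function `(t)` returning the distribution function,
#'   or `NULL` if unavailable.
#' @param support Numeric `c(lo, hi)` with `lo < hi`; all mass lies inside.
#' @return An object of class `"time_density"`.
#' @export
time_density <- function(pdf, cdf = NULL, support) {
  stopifnot(is.function(pdf), length(support) == 2L,
            support[1] < support[2])
  structure(list(pdf = pdf, cdf = cdf,
                 support = as.numeric(support)),
            class = "time_density")
}

#' Truncated-normal measurement-time density
#'
#' Normal kernel with mean `t_hat` and standard deviation `sd`, restricted to
#' `[lo, hi]` and renormalized.  This is the time model used in both worked
#' examples: the motivating example uses `sd = 0.3` truncated at
#' `t_hat +- 1` (and at the initial time), the leucine study uses
#' `sd = 0.001` h truncated at `t_hat +- 0.01` h.
#'
#' @param t_hat Intended (nominal) measurement time (h).
#' @param sd Standard deviation of the untruncated kernel (h).
#' @param lo,hi Truncation bounds (h), `lo < hi`.
#' @return A [time_density()].
#' @export
truncated_normal_time_density <- function(t_hat, sd, lo, hi) {
  stopifnot(sd > 0)
  if (!(lo < hi)) stop("empty support: need lo < hi")
  plo <- stats::pnorm(lo, t_hat, sd)
  phi <- stats::pnorm(hi, t_hat, sd)
  Z <- phi - plo
  if (Z <= 0) stop("truncation interval carries no mass")
  force(t_hat); force(sd)
  time_density(
    pdf = function(t) ifelse(t < lo | t > hi, 0,
                             stats::dnorm(t, t_hat, sd) / Z),
    cdf = function(t) pmin(1, pmax(0, (stats::pnorm(t, t_hat, sd) - plo) / Z)),
    support = c(lo, hi))
}

#' A single observation with value density and time density
#'
#' @param index Integer observation label `j`.
#' @param value Observed value `y_j` (numeric).
#' @param value_log_density Function `(y, X, t)` returning the log of the
#'   conditional observation density \eqn{g_j(y \mid x_t, t)} for each row of
#'   the particle-state matrix `X` (an `N`-vector; must also accept a single
#'   state vector as a 1-row matrix).
#' @param time_density A [time_density()]; for the standard filter with known
#'   times, pass `fixed_time` instead.
#' @param fixed_time Known measurement time (h) for standard filtering;
#'   `NA` when the time is uncertain.
#' @return An object of class `"observation"`.
#' @export
observation <- function(index, value, value_log_density,
                        time_density = NULL, fixed_time = NA_real_) {
  stopifnot(is.function(value_log_density))
  structure(list(index = index, value = value,
                 value_log_density = value_log_density,
                 time_density = time_density,
                 fixed_time = fixed_time),
            class = "observation")
}

#' Gaussian observation log-density
#'
#' Log-density of a measurement \eqn{y \sim N(q, \sigma_y^2)} where `q` is the
#' observed state coordinate.
#'
#' @param y Measured value.
#' @param q State value(s) (vectorized).
#' @param sigma_y Measurement standard deviation, `> 0`.
#' @return Log-density, vectorized over `q`.
#' @export
gaussian_value_log_density <- function(y, q, sigma_y) {
  if (sigma_y <= 0) stop("sigma_y must be > 0")
  stats::dnorm(y, mean = q, sd = sigma_y, log = TRUE)
}

#' Log-normal tracer/tracee ratio observation log-density
#'
#' The leucine output model: the measured value is
#' \eqn{y_1 = p_1 (q_1/Q_1)\,\xi} with \eqn{\xi \sim \mathrm{LogN}(0,\sigma^2)},
#' i.e. \eqn{\log y_1 \sim N(\log(p_1 q_1 / Q_1), \sigma^2)}, including the
#' \eqn{1/y_1} Jacobian.  Non-positive tracer mass `q1` makes the observation
#' impossible and yields `-Inf` (documented behaviour, not an error): particles
#' whose Euler path has wandered non-positive are self-penalized.
#'
#' @param y1 Measured ratio, `> 0`.
#' @param q1 Tracer mass in the plasma compartment (mg), vectorized.
#' @param Q1 Tracee steady-state mass (mg), `> 0`, vectorized or scalar.
#' @param p1 Plasma proportion (dimensionless fraction).
#' @param sigma Log-scale noise sd, `> 0`.
#' @return Log-density, vectorized over `q1` (and `Q1`).
#' @export
lognormal_ratio_log_density <- function(y1, q1, Q1, p1, sigma) {
  stopifnot(y1 > 0, sigma > 0)
  out <- rep(-Inf, length(q1))
  ok <- is.finite(q1) & q1 > 0 & Q1 > 0
  if (any(ok)) {
    mu <- log(p1) + log(q1[ok]) - log(if (length(Q1) > 1) Q1[ok] else Q1)
    out[ok] <- stats::dnorm(log(y1), mu, sigma, log = TRUE) - log(y1)
  }
  out
}
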