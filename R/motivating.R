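#' Configuration of the one-state linear SDE example
#'
#' The illustrative example: a scalar mean-reverting SDE
#' \deqn{dq = (-\alpha q + \beta)\,dt + \sigma\,dW_t}
#' with log-normal initial state, Gaussian measurements
#' \eqn{y_j \sim N(q(T_j), \sigma_y^2)}, and truncated-normal measurement
#' times centred at the intended times.  Defaults are the example's study
#' conditions (true \eqn{\alpha = 1}, \eqn{\beta = 3}, \eqn{\sigma = 0.05},
#' \eqn{q(0) \sim \mathrm{LogN}(\log 1, 0.1^2)}, \eqn{\sigma_y = 0.005},
#' time sd 0.3 h truncated at \eqn{\hat t_j \pm 1} and at \eqn{t_0}).
#'
#' @param alpha,beta True drift parameters (1/h and state-units/h).
#' @param sigma State diffusion (state-units per sqrt-hour).
#' @param mu_q0,sigma_q0 Log-mean and log-sd of the initial state.
#' @param sigma_y Measurement value sd.
#' @param intended_times Intended measurement times \eqn{\hat t_j} (h).
#' @param time_sd Sd of the truncated-normal time densities (h).
#' @param support_halfwidth Truncation halfwidth around \eqn{\hat t_j} (h).
#' @param t0 Initial time (h); time supports are also truncated here.
#' @return A list of class `"motivating_config"`.
#' @export
motivating_config <- function(alpha = 1, beta = 3, sigma = 0.05,
                              mu_q0 = log(1), sigma_q0 = 0.1,
                              sigma_y = 0.005,
                              intended_times = c(0.5, 1, 2, 4),
                              time_sd = 0.3, support_halfwidth = 1,
                              t0 = 0) {
  structure(as.list(environment()), class = "motivating_config")
}

#' State-space models for the one-state example
#'
#' `motivating_model()` returns the plain one-state model at fixed
#' parameters (used for data generation and simulation runs);
#' `motivating_estimation_model()` returns the augmented model
#' `(q, alpha, beta)` for Bayesian estimation runs, with log-normal priors
#' \eqn{\alpha \sim \mathrm{LogN}(\log 2, 1)},
#' \eqn{\beta \sim \mathrm{LogN}(\log 6, 1)} and geometric artificial
#' parameter noise with schedule \eqn{\sigma_\theta(t) = 5.43/(t+3.29)^2}.
#'
#' @param cfg A [motivating_config()].
#' @param alpha,beta Fixed parameter values (default: the config's truths).
#' @return A [state_space_model()].
#' @export
motivating_model <- function(cfg = motivating_config(),
                             alpha = cfg$alpha, beta = cfg$beta) {
  sigma <- cfg$sigma
  state_space_model(
    dim = 1,
    drift = function(x, t) -alpha * x[1] + beta,
    diffusion = function(x, t) sigma,
    sample_initial = function(n)
      matrix(stats::rlnorm(n, cfg$mu_q0, cfg$sigma_q0), n, 1),
    step_particles = function(X, t, dt)
      X + (-alpha * X + beta) * dt +
        sigma * sqrt(dt) * matrix(stats::rnorm(nrow(X)), nrow(X), 1),
    names = "q")
}

#' @rdname motivating_model
#' @param prior_alpha,prior_beta Prior samplers `function(n)`.
#' @param dynamics_alpha,dynamics_beta [artificial_dynamics()] for the two
#'   parameters (default: the geometric `5.43/(t+3.29)^2` schedule).
#' @export
motivating_estimation_model <- function(cfg = motivating_config(),
    prior_alpha = function(n) stats::rlnorm(n, log(2), 1),
    prior_beta = function(n) stats::rlnorm(n, log(6), 1),
    dynamics_alpha = artificial_dynamics("geometric", a_theta = 5.43,
                                         b_theta = -3.29),
    dynamics_beta = artificial_dynamics("geometric", a_theta = 5.43,
                                        b_theta = -3.29)) {
  sigma <- cfg$sigma
  build_augmented_model(
    state_dim = 1, state_names = "q",
    drift = function(Q, Th, t) -Th[, 1] * Q[, 1] + Th[, 2],
    diffusion = function(Q, Th, t) matrix(sigma, nrow(Q), 1),
    sample_q0 = function(n)
      matrix(stats::rlnorm(n, cfg$mu_q0, cfg$sigma_q0), n, 1),
    priors = list(alpha = prior_alpha, beta = prior_beta),
    dynamics = list(alpha = dynamics_alpha, beta = dynamics_beta))
}

#' Observation list for the one-state example
#'
#' Builds [observation()] objects for measurement values at the intended
#' times: with `uncertain_times = TRUE` each observation carries its
#' truncated-normal [time_density()] (support
#' \eqn{[\max(t_0, \hat t_j - 1), \hat t_j + 1]}); otherwise the intended
#' times are treated as exact (`fixed_time`), which is the "lumped"
#' standard-filter setup, usually combined with an inflated `sigma_y`.
#'
#' @param values Measured values `y_j`.
#' @param cfg A [motivating_config()] (supplies intended times and the time
#'   model).
#' @param sigma_y Measurement value sd used by the filter (defaults to the
#'   config's; the lumped runs pass larger values).
#' @param uncertain_times Build MTU time densities (default) or fixed times.
#' @return List of [observation()]s.
#' @export
motivating_observations <- function(values, cfg = motivating_config(),
                                    sigma_y = cfg$sigma_y,
                                    uncertain_times = TRUE) {
  stopifnot(length(values) == length(cfg$intended_times))
  lapply(seq_along(values), function(j) {
    y <- values[j]; that <- cfg$intended_times[j]
    vld <- function(y, X, t) gaussian_value_log_density(y, X[, 1], sigma_y)
    if (uncertain_times) {
      observation(j, y, vld,
        time_density = truncated_normal_time_density(
          that, cfg$time_sd,
          lo = max(cfg$t0, that - cfg$support_halfwidth),
          hi = that + cfg$support_halfwidth))
    } else {
      observation(j, y, vld, fixed_time = that)
    }
  })
}

#' The example's bundled reference measurements
#'
#' The four measurement values obtained from one simulation run of the true
#' model at intended times 0.5, 1, 2, 4 h, used throughout the package's
#' estimation examples and tests.
#'
#' @return List with `times` (intended times, h) and `values`.
#' @export
motivating_example_data <- function() {
  list(times = c(0.5, 1, 2, 4),
       values = c(1.083346, 2.550290, 2.700863, 2.949450))
}
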