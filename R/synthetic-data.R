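#' Generate a synthetic dataset for the one-state example
#'
#' Emulates the example's study design: simulate one state path with the
#' true parameters on a fine Euler grid, draw an actual measurement time
#' \eqn{T_j} from each truncated-normal time density, then draw the
#' measurement value \eqn{y_j \sim N(q(T_j), \sigma_y^2)}.
#'
#' @param cfg A [motivating_config()].
#' @param t_end Simulation horizon (h).
#' @param dt Simulation stepsize (h).
#' @return List with `path` (data frame `time`, `q`), `times` (sampled
#'   actual measurement times \eqn{T_j}), `intended_times` and `values`.
#' @export
generate_motivating_dataset <- function(cfg = motivating_config(),
                                        t_end = 10, dt = 1e-3) {
  if (t_end < max(cfg$intended_times) + cfg$support_halfwidth)
    stop("`t_end` must cover every measurement-time support")
  grid <- seq(cfg$t0, t_end, by = dt)
  path <- simulate_path(motivating_model(cfg), grid)[, 1]
  times <- vapply(cfg$intended_times, function(that) {
    lo <- max(cfg$t0, that - cfg$support_halfwidth)
    hi <- that + cfg$support_halfwidth
    u <- stats::runif(1, stats::pnorm(lo, that, cfg$time_sd),
                      stats::pnorm(hi, that, cfg$time_sd))
    stats::qnorm(u, that, cfg$time_sd)
  }, numeric(1))
  q_at <- stats::approx(grid, path, xout = times)$y
  values <- stats::rnorm(length(times), q_at, cfg$sigma_y)
  list(path = data.frame(time = grid, q = path),
       times = times, intended_times = cfg$intended_times, values = values)
}

#' Generate a synthetic two-group leucine population
#'
#' Emulates the study design of the leucine application: each patient
#' receives a tracer bolus `u10` at `t = 0`, carries a log-normal random
#' effect \eqn{\zeta_p = e^{\eta_p}}, \eqn{\eta_p \sim N(0, \sigma_\eta^2)},
#' on the group degradation rate, the tracer follows the mass-conserving
#' four-compartment SDE, and the measured tracer/tracee ratios follow the
#' log-normal output model at times jittered by the measurement-time
#' density.  The records serialize through [write_population_file()]; the
#' generating truths are attached as the `"truth"` attribute (never written
#' to the data file).
#'
#' @param params True [leucine_params()].
#' @param P_control,P_diabetes Group sizes (`>= 0`).
#' @param times Nominal measurement schedule (h).
#' @param u10 Tracer bolus (mg).
#' @param sigma_eta Random-effect sd.
#' @param time_sd,time_halfwidth Measurement-time jitter (h).
#' @param dt Euler stepsize for the simulated tracer paths (h).
#' @return List of patient records with attribute `"truth"` (params,
#'   per-patient `eta`).
#' @export
generate_leucine_population <- function(params = leucine_params(),
                                        P_control = 2, P_diabetes = 2,
                                        times = c(0.05, 0.1, 0.15, 0.2,
                                                  0.3, 0.5, 0.75, 0.95),
                                        u10 = 50, sigma_eta = 0.5,
                                        time_sd = 0.001,
                                        time_halfwidth = 0.01,
                                        dt = 1e-3) {
  stopifnot(P_control >= 0, P_diabetes >= 0)
  groups <- c(rep("control", P_control), rep("diabetes", P_diabetes))
  etas <- numeric(length(groups))
  records <- vector("list", length(groups))
  if (!length(groups)) {
    attr(records, "truth") <- list(params = params, eta = etas)
    return(records)
  }
  t_end <- max(times) + time_halfwidth
  grid <- seq(0, t_end, by = dt)
  for (p in seq_along(groups)) {
    eta <- if (sigma_eta > 0) stats::rnorm(1, 0, sigma_eta) else 0
    etas[p] <- eta
    k01p <- patient_k01(groups[p], exp(eta), params$k01_c, params$k01_d)
    K <- leucine_K(params, k01p)
    B <- K %*% diag(params$sigma_i)
    q <- matrix(NA_real_, length(grid), 4)
    q[1, ] <- c(u10, 0, 0, 0)
    for (k in 2L:length(grid))
      q[k, ] <- q[k - 1, ] + drop(K %*% q[k - 1, ]) * dt +
        sqrt(dt) * drop(B %*% stats::rnorm(4))
    tj <- vapply(times, function(that) {
      lo <- max(0, that - time_halfwidth); hi <- that + time_halfwidth
      u <- stats::runif(1, stats::pnorm(lo, that, time_sd),
                        stats::pnorm(hi, that, time_sd))
      stats::qnorm(u, that, time_sd)
    }, numeric(1))
    q1_at <- stats::approx(grid, q[, 1], xout = tj)$y
    Q1 <- steady_state_Q1(params, k01p)
    ratio <- params$p1 * pmax(q1_at, 1e-12) / Q1
    values <- ratio * exp(stats::rnorm(length(tj), 0, params$sigma_y1))
    records[[p]] <- list(id = sprintf("%s%02d", substr(groups[p], 1, 1), p),
                         group = groups[p], u10 = u10,
                         times = times, values = values)
  }
  attr(records, "truth") <- list(params = params, eta = etas)
  records
}
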