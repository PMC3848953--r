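#' One Euler update of the per-observation partial-weight accumulators
#'
#' The MTU filter carries, per observation `j`, the time-density mass
#' \eqn{\bar\gamma_{j,t} = \int_{t_0}^t \gamma_j} and the path-dependent
#' accumulator \eqn{\bar w_{j,t} = \int_{t_0}^t g_j(y_j|x_s,s)\,\gamma_j(s)\,ds},
#' so the per-observation weight factor is the numerically robust split form
#' \eqn{w_{j,t} = 1 - \bar\gamma_{j,t} + \bar w_{j,t}}.  One step advances
#' both accumulators with the exact time-density mass crossed when the
#' analytic cdf \eqn{\Gamma_j} is available:
#' \eqn{\bar w \mathrel{+}= g_j(y_j|x_t,t)\,[\Gamma_j(t+\Delta t) -
#' \Gamma_j(t)]} and \eqn{\bar\gamma = \Gamma_j(t+\Delta t)} (left-endpoint
#' states, so the scheme is first-order in the slowly varying \eqn{g} while
#' integrating the possibly sharply peaked \eqn{\gamma_j} exactly); without a
#' cdf both fall back to left-endpoint Euler,
#' \eqn{\gamma_j(t)\,\Delta t}.  Outside the support of \eqn{\gamma_j} both
#' are unchanged.
#'
#' @param gamma_bar Current cdf mass \eqn{\bar\gamma_{j,t}} (scalar in `[0,1]`).
#' @param w_bar Current accumulator values, one per particle (nonnegative).
#' @param log_g Log observation densities \eqn{\log g_j(y_j|x^i_t, t)} at the
#'   current states and time (same length as `w_bar`); ignored where
#'   \eqn{\gamma_j(t) = 0}.
#' @param td The observation's [time_density()].
#' @param t Current time (h).
#' @param dt Stepsize (h), `> 0`.
#' @return List with updated `gamma_bar` and `w_bar`.
#' @export
partial_weight_step <- function(gamma_bar, w_bar, log_g, td, t, dt) {
  stopifnot(dt > 0)
  if (!is.null(td$cdf)) {
    gamma_new <- td$cdf(t + dt)
    dmass <- gamma_new - td$cdf(t)
  } else {
    dmass <- td$pdf(t) * dt
    gamma_new <- min(1, gamma_bar + dmass)
  }
  if (dmass > 0)
    w_bar <- w_bar + exp(log_g) * dmass
  list(gamma_bar = gamma_new, w_bar = w_bar)
}

#' Combined MTU particle weight
#'
#' The (resampling-corrected) weight of an MTU particle,
#' \deqn{w = \frac{\prod_j (1 - \bar\gamma_j + \bar w_j)}{\bar v},}
#' where \eqn{\bar v} is the particle's cumulative product of selection
#' weights from past resampling events.  Computed in log space; a factor that
#' is exactly zero short-circuits to weight 0 (log-weight `-Inf`) without
#' poisoning the other factors.
#'
#' @param gamma_bar Vector of cdf masses, one per observation.
#' @param w_bar `N x M` matrix (or `M`-vector for a single particle) of
#'   accumulators.
#' @param log_v_bar Log cumulative selection-weight products (default 0).
#' @param log Return log-weights (default `FALSE`).
#' @return Vector of `N` combined weights (or log-weights).
#' @export
combined_weight <- function(gamma_bar, w_bar, log_v_bar = 0, log = FALSE) {
  W <- if (is.null(dim(w_bar))) matrix(w_bar, nrow = 1) else w_bar
  stopifnot(ncol(W) == length(gamma_bar))
  fac <- sweep(W, 2, 1 - gamma_bar, "+")
  fac[fac < 0] <- 0
  lw <- rowSums(log(fac)) - log_v_bar
  lw[is.nan(lw)] <- -Inf
  if (log) lw else exp(lw)
}

#' Predicted ESS after a candidate partial-weight update
#'
#' Applies [partial_weight_step()] with a candidate stepsize to a *copy* of
#' the accumulators — without advancing any states — and returns the ESS of
#' the resulting combined weights.  This is exactly the ESS the filter would
#' record after accepting the step, because the weight update uses the
#' left-endpoint states, which are already known (valid when sampling from
#' the model kernel itself).
#'
#' @param X `N x d` matrix of current particle states.
#' @param gamma_bar,w_bar,log_v_bar Current accumulators as in
#'   [combined_weight()].
#' @param observations List of [observation()]s with time densities (the full
#'   list; inactive ones contribute unchanged factors).
#' @param t Current time (h).
#' @param dt Candidate stepsize (h).
#' @return The predicted ESS.
#' @export
predict_ess <- function(X, gamma_bar, w_bar, log_v_bar, observations, t, dt) {
  gb <- gamma_bar; wb <- w_bar
  for (j in seq_along(observations)) {
    td <- observations[[j]]$time_density
    if (gb[j] >= 1 || t >= td$support[2]) next
    o <- observations[[j]]
    lg <- if (td$pdf(t) > 0) o$value_log_density(o$value, X, t) else
      rep(0, nrow(X))
    up <- partial_weight_step(gb[j], wb[, j], lg, td, t, dt)
    gb[j] <- up$gamma_bar; wb[, j] <- up$w_bar
  }
  lw <- combined_weight(gb, wb, log_v_bar, log = TRUE)
  if (all(!is.finite(lw))) return(1)   # worst case: candidate kills the cloud
  ess_log(lw)
}

#' ESS-controlled adaptive stepsize
#'
#' Produces the accepted stepsize for the next MTU step.  The initial guess
#' interpolates linearly between `dt_max` (ESS unchanged over the last
#' accepted step) and `dt_min` (ESS dropped by `N - 1`, the largest drop
#' possible); it is then capped at `cap` (distance to the next time-density
#' support boundary or to the horizon, so those are always grid points) and
#' halved while the predicted ESS falls more than `rel_drop` (default 10%)
#' below the current ESS, until acceptable or the `dt_min` floor is reached.
#'
#' @param ess_now Current ESS.
#' @param ess_prev ESS at the previous accepted step.
#' @param n_particles Particle count `N`.
#' @param dt_min,dt_max Stepsize bounds (h), `0 < dt_min <= dt_max`.
#' @param rel_drop Tolerated relative ESS drop per step, in `(0, 1)`.
#' @param predict Function `(dt)` returning the predicted ESS (see
#'   [predict_ess()]); may be `NULL` to skip the halving loop.
#' @param cap Upper bound from splitting at support boundaries / horizon
#'   (h, default `Inf`); may undercut `dt_min` when a boundary is closer
#'   than the floor.
#' @return The accepted stepsize (h).
#' @export
adaptive_stepsize <- function(ess_now, ess_prev, n_particles,
                              dt_min, dt_max, rel_drop = 0.1,
                              predict = NULL, cap = Inf) {
  stopifnot(dt_min > 0, dt_min <= dt_max, rel_drop > 0, rel_drop < 1)
  drop <- min(max(ess_prev - ess_now, 0), n_particles - 1)
  dt <- dt_max - (dt_max - dt_min) * drop / (n_particles - 1)
  dt <- min(dt, cap)
  if (!is.null(predict)) {
    while (dt > dt_min && predict(dt) < (1 - rel_drop) * ess_now)
      dt <- dt / 2
    if (dt < dt_min) dt <- min(dt_min, cap)
  }
  dt
}

#' Corrected marginal-likelihood estimate of the MTU filter
#'
#' The data-likelihood estimate at the current time,
#' \deqn{\hat Z_t = \frac{1}{N^{\ell+1}} \prod_{\lambda=1}^{\ell}
#'   \Big(\sum_i v^i_{s_\lambda}\Big) \sum_i w_t^i,}
#' where the \eqn{w_t^i} are the resampling-corrected combined weights and
#' the product runs over the \eqn{\ell} past resampling events.  With no
#' resampling this is the plain mean of the combined weights.  Maintained in
#' log space.
#'
#' @param log_weights Log corrected combined weights (length `N`).
#' @param log_sum_v Log of the summed selection weights, one entry per past
#'   resampling event (`numeric(0)` if none).
#' @param n_particles Particle count `N`.
#' @param log Return the log estimate (default `FALSE`).
#' @return The likelihood estimate \eqn{\hat Z_t} (or its log).
#' @export
mtu_likelihood <- function(log_weights, log_sum_v = numeric(0),
                           n_particles = length(log_weights), log = FALSE) {
  ll <- sum(log_sum_v - log(n_particles)) +
    log_sum_exp(log_weights) - log(n_particles)
  if (log) ll else exp(ll)
}

#' MTU particle filter (random measurement times)
#'
#' Continuous-time particle filter for observations whose measurement times
#' are random with known densities.  Per accepted step: the stepsize is chosen
#' adaptively from the ESS (see [adaptive_stepsize()]), states advance by one
#' Euler--Maruyama step, all partial-weight accumulators are updated
#' ([partial_weight_step()]), combined weights, ESS and the corrected
#' likelihood estimate ([mtu_likelihood()]) are recorded, and the cloud is
#' resampled whenever the ESS falls below the threshold, using the current
#' combined weights as selection weights.  At a resampling event the
#' cumulative selection-weight products \eqn{\bar v^i} are selected alongside
#' the states and multiplied by the selection weight of the chosen index, so
#' the corrected weights are all 1 immediately afterwards.
#'
#' @param model A [state_space_model()].
#' @param observations List of [observation()]s carrying [time_density()]s
#'   whose supports lie within `[t0, t_end]`.
#' @param n_particles Particle count `N`.
#' @param t0,t_end Filtering horizon (h).
#' @param dt_min,dt_max Stepsize bounds (h).
#' @param rel_drop Tolerated relative per-step ESS drop (default 0.10).
#' @param resample_threshold ESS threshold (default `N/2`).
#' @param scheme Resampling scheme (default systematic).
#' @param track Coordinate indices whose weighted quantiles are recorded.
#' @param record_n Approximate number of quantile record times.
#' @param w_quadrature How the \eqn{\bar w} integral is advanced per step:
#'   `"euler"` uses the left-endpoint product \eqn{\gamma(t)\,\Delta t} (the
#'   filter's basic Euler update rule); `"mass"` multiplies the left-endpoint
#'   observation density by the exact cdf increment
#'   \eqn{\Gamma(t+\Delta t) - \Gamma(t)}, which is required when the time
#'   density is too narrow for the step grid to resolve (a left-Riemann sum
#'   over a near-point-mass spike misestimates its mass by order one).  The
#'   default `"auto"` applies the rule per observation: densities with an
#'   analytic cdf whose support spans fewer than 50 maximal steps use
#'   `"mass"`, all others `"euler"`.  Densities without a cdf always use
#'   `"euler"`.
#' @return A `filter_trace` object with per-step times, ESS, cumulative
#'   log-likelihood and accepted stepsizes, thinned weighted quantiles, the
#'   resampling event log, and the final weighted cloud.
#' @export
mtu_pf <- function(model, observations, n_particles = 10000,
                   t0 = 0, t_end,
                   dt_max = 1e-2, dt_min = 1e-6, rel_drop = 0.1,
                   resample_threshold = n_particles / 2,
                   scheme = "systematic",
                   track = seq_len(model$dim),
                   record_n = 201,
                   w_quadrature = c("auto", "euler", "mass")) {
  w_quadrature <- match.arg(w_quadrature)
  M <- length(observations)
  supports <- vapply(observations, function(o) o$time_density$support,
                     numeric(2))
  if (missing(t_end)) t_end <- if (M) max(supports[2, ]) else t0 + dt_max
  if (M && (any(supports[1, ] < t0) || any(supports[2, ] > t_end)))
    stop("every time-density support must lie within [t0, t_end]")
  boundaries <- sort(unique(c(as.numeric(supports), t_end)))
  use_mass <- vapply(observations, function(o) {
    has_cdf <- !is.null(o$time_density$cdf)
    switch(w_quadrature,
           euler = FALSE,
           mass = has_cdf,
           auto = has_cdf && diff(o$time_density$support) < 50 * dt_max)
  }, logical(1))

  X <- model$sample_initial(n_particles)
  colnames(X) <- model$names
  gamma_bar <- rep(0, M)
  w_bar <- matrix(0, n_particles, M)
  log_v_bar <- rep(0, n_particles)
  log_corr <- 0          # sum over events of log(sum v) - log N
  log_sum_v <- numeric(0)

  qprobs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  rec_times <- seq(t0, t_end, length.out = max(2, record_n))
  acc <- new.env(parent = emptyenv())
  acc$n <- 0L; acc$cap <- 1024L
  acc$time <- acc$ess <- acc$loglik <- acc$dt <- numeric(1024L)
  acc$means <- matrix(NA_real_, 1024L, length(track))
  push <- function(tm, e, ll, d) {
    if (acc$n == acc$cap) {
      acc$cap <- acc$cap * 2L
      for (f in c("time", "ess", "loglik", "dt"))
        acc[[f]] <- c(acc[[f]], numeric(acc$cap / 2L))
      acc$means <- rbind(acc$means,
                         matrix(NA_real_, acc$cap / 2L, length(track)))
    }
    acc$n <- acc$n + 1L
    acc$time[acc$n] <- tm; acc$ess[acc$n] <- e
    acc$loglik[acc$n] <- ll; acc$dt[acc$n] <- d
    w <- exp(logw - max(logw))
    acc$means[acc$n, ] <- colSums(X[, track, drop = FALSE] * w) / sum(w)
  }
  qt_list <- list(); qt_times <- numeric(0); next_rec <- 1L
  events <- list()

  logw <- rep(0, n_particles)
  t <- t0
  e_now <- e_prev <- n_particles
  push(t0, n_particles, 0, NA_real_)

  # grid times accumulate floating-point error over thousands of additions;
  # boundary bookkeeping therefore snaps within a tolerance far above the
  # accumulated error and far below any usable stepsize
  tol <- 1e-9
  while (t < t_end - tol) {
    # observations whose support has been entered but not exhausted
    live <- which(gamma_bar < 1 & supports[2, ] > t + tol)
    hot <- live[supports[1, live] <= t + tol]     # pdf possibly > 0 at t
    log_g <- lapply(hot, function(j) {
      o <- observations[[j]]
      o$value_log_density(o$value, X, t)
    })
    names(log_g) <- as.character(hot)
    pdf_t <- vapply(hot, function(j)
      observations[[j]]$time_density$pdf(t), numeric(1))

    cap <- min(boundaries[boundaries > t + tol]) - t
    base_lw <- logw
    predict_fn <- if (length(hot)) function(dt) {
      lw <- base_lw
      for (k in seq_along(hot)) {
        j <- hot[k]
        td <- observations[[j]]$time_density
        if (!is.null(td$cdf)) {
          gb_new <- td$cdf(t + dt)
          dmass <- if (use_mass[j]) gb_new - gamma_bar[j] else pdf_t[k] * dt
        } else {
          dmass <- pdf_t[k] * dt
          gb_new <- min(1, gamma_bar[j] + dmass)
        }
        if (dmass <= 0) next
        wb_new <- w_bar[, j] + exp(log_g[[k]]) * dmass
        fac_old <- pmax(1 - gamma_bar[j] + w_bar[, j], 0)
        fac_new <- pmax(1 - gb_new + wb_new, 0)
        lw <- lw + log(fac_new) - log(fac_old)
      }
      # entering supports at t+dt only changes factors from the *next* step
      lw[is.nan(lw)] <- -Inf
      if (all(!is.finite(lw))) 1 else ess_log(lw)
    } else NULL
    dt <- adaptive_stepsize(e_now, e_prev, n_particles, dt_min, dt_max,
                            rel_drop, predict_fn, cap)

    # advance states, then accumulate the left-endpoint weight increments
    X <- model$step_particles(X, t, dt)
    for (k in seq_along(hot)) {
      j <- hot[k]
      td <- observations[[j]]$time_density
      dmass <- if (use_mass[j] && !is.null(td$cdf))
        td$cdf(t + dt) - gamma_bar[j] else pdf_t[k] * dt
      if (dmass > 0)
        w_bar[, j] <- w_bar[, j] + exp(log_g[[k]]) * dmass
    }
    for (j in live) {
      td <- observations[[j]]$time_density
      gamma_bar[j] <- if (!is.null(td$cdf)) td$cdf(t + dt) else
        min(1, gamma_bar[j] + td$pdf(t) * dt)
    }
    t <- t + dt
    hit <- boundaries[abs(boundaries - t) <= tol]
    if (length(hit)) t <- hit[1]    # land exactly on boundaries
    logw <- combined_weight(gamma_bar, w_bar, log_v_bar, log = TRUE)
    if (all(!is.finite(logw))) {
      err <- simpleError(sprintf(
        "particle degeneracy: all combined weights vanished at t = %g", t))
      n <- acc$n
      err$trace <- filter_trace(acc$time[1:n], acc$ess[1:n], acc$loglik[1:n],
                                acc$dt[1:n], qt_times, NULL, events,
                                n_particles)
      stop(err)
    }
    e <- ess_log(logw)
    e_pre <- e              # pre-resampling ESS: the degeneracy diagnostic
    loglik <- log_corr + log_sum_exp(logw) - log(n_particles)

    if (e < resample_threshold) {
      lw_max <- max(logw)
      idx <- resample_indices(exp(logw - lw_max), n_particles, scheme)
      lsv <- log_sum_exp(logw)
      events[[length(events) + 1L]] <-
        data.frame(time = t, ess_before = e, ess_after = n_particles,
                   log_sum_v = lsv)
      log_sum_v <- c(log_sum_v, lsv)
      log_corr <- log_corr + lsv - log(n_particles)
      X <- X[idx, , drop = FALSE]
      w_bar <- w_bar[idx, , drop = FALSE]
      log_v_bar <- log_v_bar[idx] + logw[idx]
      logw <- rep(0, n_particles)  # v = w: corrected weights are all 1
      e <- n_particles
    }
    e_prev <- e_now
    e_now <- e              # post-resampling ESS drives the stepsize control
    push(t, e_pre, loglik, dt)
    while (next_rec <= length(rec_times) && t >= rec_times[next_rec] - 1e-12) {
      w <- exp(logw - max(logw))
      qt_list[[length(qt_list) + 1L]] <-
        vapply(track, function(j) weighted_quantile(X[, j], w, qprobs),
               numeric(length(qprobs)))
      qt_times <- c(qt_times, t)
      next_rec <- next_rec + 1L
    }
  }

  n <- acc$n
  quants <- if (length(qt_list)) {
    q <- array(NA_real_, c(length(qt_list), length(track), length(qprobs)),
               dimnames = list(NULL, model$names[track], paste0("q", qprobs)))
    for (r in seq_along(qt_list)) q[r, , ] <- t(qt_list[[r]])
    q
  } else NULL
  means <- acc$means[1:n, , drop = FALSE]
  colnames(means) <- model$names[track]
  filter_trace(acc$time[1:n], acc$ess[1:n], acc$loglik[1:n], acc$dt[1:n],
               qt_times, quants, events, n_particles,
               final = list(states = X, log_weights = logw,
                            log_sum_v = log_sum_v),
               means = means)
}
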