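#' Effective sample size of a weight vector
#'
#' \eqn{n_{ESS} = 1 / \sum_i \tilde w_i^2} with normalized weights
#' \eqn{\tilde w_i = w_i / \sum_\nu w_\nu}.  Lies in `[1, N]`; equals `N`
#' exactly when all weights are equal and approaches 1 as the weights
#' degenerate onto a single particle.
#'
#' @param weights Nonnegative weight vector with at least one positive entry.
#' @return The ESS estimate.
#' @export
ess <- function(weights) {
  s <- sum(weights)
  if (!is.finite(s) || s <= 0)
    stop("weight degeneracy: all weights are zero")
  w <- weights / s
  1 / sum(w^2)
}

# ESS from log-weights, guarding against under/overflow.
ess_log <- function(log_weights) {
  m <- max(log_weights)
  if (!is.finite(m)) stop("weight degeneracy: all weights are zero")
  ess(exp(log_weights - m))
}

#' Resampling index selection
#'
#' Draws `n` particle indices with marginal probabilities proportional to the
#' selection weights, by multinomial, stratified or systematic selection
#' (systematic is the package default throughout, having the lowest variance).
#'
#' @param selection_weights Nonnegative, not all zero.
#' @param n Number of draws (default `length(selection_weights)`).
#' @param scheme One of `"systematic"`, `"stratified"`, `"multinomial"`.
#' @return Integer vector of selected indices.
#' @export
resample_indices <- function(selection_weights,
                             n = length(selection_weights),
                             scheme = c("systematic", "stratified",
                                        "multinomial")) {
  scheme <- match.arg(scheme)
  s <- sum(selection_weights)
  if (!is.finite(s) || s <= 0)
    stop("weight degeneracy: all selection weights are zero")
  p <- selection_weights / s
  u <- switch(scheme,
    multinomial = sort(stats::runif(n)),
    stratified  = (seq_len(n) - stats::runif(n)) / n,
    systematic  = (seq_len(n) - stats::runif(1)) / n)
  findInterval(u, cumsum(p), left.open = TRUE) + 1L
}

#' Resample a weighted particle set with weight correction
#'
#' Replaces states by selected states and corrects the unnormalized weights by
#' `w[idx] / v[idx]`, which removes the bias introduced by selection.  With the
#' classical choice `v = w` all corrected weights equal 1.
#'
#' @param states `N x d` matrix of particle states (or a vector).
#' @param weights Unnormalized particle weights.
#' @param selection_weights Nonnegative selection weights `v` (default: the
#'   particle weights themselves).
#' @param scheme Passed to [resample_indices()].
#' @return List with `states`, `weights` (corrected) and the selection map
#'   `indices`.
#' @export
resample <- function(states, weights, selection_weights = weights,
                     scheme = "systematic") {
  vec <- is.null(dim(states))
  X <- if (vec) matrix(states, ncol = 1) else states
  idx <- resample_indices(selection_weights, nrow(X), scheme)
  w <- weights[idx] / selection_weights[idx]
  list(states = if (vec) X[idx, 1] else X[idx, , drop = FALSE],
       weights = w, indices = idx)
}

#' Recursive data-likelihood ratio update
#'
#' One step of the recursive marginal-likelihood estimator: returns the
#' estimate of \eqn{Z_{t_k}/Z_{t_{k-1}}},
#' \deqn{\frac{\sum_i \varrho_i\, g_i\, w_i^{prev}}{\sum_i w_i^{prev}},}
#' computed in log space. The cumulative estimate starts at
#' \eqn{\hat Z_{t_0} = 1}.
#'
#' @param log_prev_weights Log unnormalized weights before the update.
#' @param log_g Log observation densities \eqn{\log g_k(y_k|x^i,t_k)}.
#' @param log_ratio Log proposal ratios (0 for the prior proposal).
#' @return The log of the likelihood ratio.
#' @export
likelihood_ratio_update <- function(log_prev_weights, log_g, log_ratio = 0) {
  stopifnot(length(log_g) == length(log_prev_weights))
  log_sum_exp(log_prev_weights + log_g + log_ratio) -
    log_sum_exp(log_prev_weights)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)   # all -Inf (or an Inf): propagate
  m + log(sum(exp(x - m)))
}

#' Self-normalized filter expectation
#'
#' \eqn{\sum_i w_i h(x_i) / \sum_i w_i} for a test function `h` applied to the
#' rows of the state matrix.
#'
#' @param states `N x d` matrix (or vector) of particle states.
#' @param weights Unnormalized weights.
#' @param h Function of a single state vector returning a scalar.
#' @return The weighted mean of `h`.
#' @export
filter_expectation <- function(states, weights, h) {
  X <- if (is.null(dim(states))) matrix(states, ncol = 1) else states
  vals <- apply(X, 1, h)
  sum(weights * vals) / sum(weights)
}

#' Weighted empirical quantiles
#'
#' Quantiles of a weighted sample: the smallest `x` whose cumulative
#' normalized weight reaches `p`.  Used for all reported parameter and state
#' summaries (medians and the 0.025/0.25/0.75/0.975 boxes).
#'
#' @param x Numeric sample values.
#' @param weights Nonnegative weights.
#' @param probs Probabilities in `[0, 1]`.
#' @return Named numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, weights,
                              probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  ord <- order(x)
  cw <- cumsum(weights[ord]) / sum(weights)
  out <- vapply(probs, function(p) x[ord][which(cw >= p - 1e-12)[1]],
                numeric(1))
  names(out) <- paste0("q", probs)
  out
}

#' Standard particle filter (known measurement times)
#'
#' Sequential importance sampling with resampling on a fixed Euler grid.
#' Weights are multiplied by the observation density at each (known)
#' measurement time; when a measurement time does not lie on the `dt` grid the
#' step is split so the update happens exactly there.  Resampling (selection
#' weights = particle weights, so corrected weights are all 1) is triggered
#' when the ESS falls below `resample_threshold`.  All weight arithmetic is in
#' log space; full degeneracy (all log-weights `-Inf`) aborts with an error
#' carrying the trace up to the failure.
#'
#' @param model A [state_space_model()].
#' @param observations List of [observation()]s with `fixed_time` set,
#'   strictly increasing in time.
#' @param n_particles Number of particles `N`.
#' @param t0,t_end Filtering horizon (h).
#' @param dt Fixed Euler stepsize (h).
#' @param resample_threshold ESS threshold (default `N/2`).
#' @param scheme Resampling scheme (default systematic).
#' @param track Integer indices of state coordinates whose weighted quantiles
#'   are recorded (default: all, capped at the model dimension).
#' @param record_n Approximate number of time points at which quantiles are
#'   recorded (ESS and log-likelihood are recorded at every grid time).
#' @return A `filter_trace` object; see [filter_trace()].
#' @export
standard_pf <- function(model, observations, n_particles = 10000,
                        t0 = 0, t_end, dt = 1e-2,
                        resample_threshold = n_particles / 2,
                        scheme = "systematic",
                        track = seq_len(model$dim),
                        record_n = 201) {
  stopifnot(dt > 0, n_particles >= 1,
            resample_threshold > 0, resample_threshold <= n_particles)
  obs_times <- vapply(observations, function(o) o$fixed_time, numeric(1))
  if (any(is.na(obs_times)))
    stop("standard_pf needs a known `fixed_time` for every observation")
  if (is.unsorted(obs_times, strictly = TRUE))
    stop("observation times must be strictly increasing")
  if (missing(t_end)) {
    if (!length(obs_times))
      stop("`t_end` is required when there are no observations")
    t_end <- max(obs_times)
  }
  stopifnot(all(obs_times > t0), all(obs_times <= t_end))

  grid <- sort(unique(c(seq(t0, t_end, by = dt), obs_times, t_end)))
  obs_at <- match(round(obs_times, 12), round(grid, 12))

  X <- model$sample_initial(n_particles)
  colnames(X) <- model$names
  logw <- if (is.null(model$proposal)) rep(0, n_particles) else
    apply(X, 1, model$proposal$initial_log_ratio)
  D <- length(grid)
  ess_tr <- loglik_tr <- numeric(D)
  rec_idx <- unique(round(seq(1, D, length.out = min(record_n, D))))
  qprobs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  quants <- array(NA_real_, c(length(rec_idx), length(track), length(qprobs)),
                  dimnames = list(NULL, model$names[track],
                                  paste0("q", qprobs)))
  events <- list()
  loglik <- 0
  means <- matrix(NA_real_, D, length(track),
                  dimnames = list(NULL, model$names[track]))
  record_means <- function(d) {
    w <- exp(logw - max(logw))
    means[d, ] <<- colSums(X[, track, drop = FALSE] * w) / sum(w)
  }
  ess_tr[1] <- ess_log(logw)
  loglik_tr[1] <- 0
  record_means(1L)
  record_quants <- function(d) {
    r <- match(d, rec_idx)
    if (!is.na(r)) {
      w <- exp(logw - max(logw))
      for (j in seq_along(track))
        quants[r, j, ] <<- weighted_quantile(X[, track[j]], w, qprobs)
    }
  }
  record_quants(1L)

  for (d in 2L:D) {
    X <- model$step_particles(X, grid[d - 1L], grid[d] - grid[d - 1L])
    k <- match(d, obs_at)
    if (!is.na(k)) {
      o <- observations[[k]]
      logg <- o$value_log_density(o$value, X, grid[d])
      loglik <- loglik + likelihood_ratio_update(logw, logg)
      logw <- logw + logg
      if (all(!is.finite(logw))) {
        err <- simpleError(sprintf(
          "particle degeneracy: all weights vanished at t = %g", grid[d]))
        err$trace <- filter_trace(grid[1:(d - 1)], ess_tr[1:(d - 1)],
                                  loglik_tr[1:(d - 1)], NULL, NULL, NULL,
                                  events, n_particles)
        stop(err)
      }
    }
    e <- ess_log(logw)
    ess_tr[d] <- e          # pre-resampling ESS: the degeneracy diagnostic
    if (e < resample_threshold) {
      w <- exp(logw - max(logw))
      idx <- resample_indices(w, n_particles, scheme)
      X <- X[idx, , drop = FALSE]
      events[[length(events) + 1L]] <-
        data.frame(time = grid[d], ess_before = e, ess_after = n_particles,
                   log_sum_v = log_sum_exp(logw))
      logw <- rep(0, n_particles)   # v = w: corrected weights are all 1
    }
    loglik_tr[d] <- loglik
    record_means(d)
    record_quants(d)
  }
  filter_trace(grid, ess_tr, loglik_tr, NULL,
               grid[rec_idx], quants, events, n_particles,
               final = list(states = X, log_weights = logw),
               means = means)
}
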