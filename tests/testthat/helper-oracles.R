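# Shared fixtures and independent oracles used across test files.

# Ornstein-Uhlenbeck moments for dq = (-alpha q + beta) dt + sigma dW, q0 fixed.
ou_mean <- function(t, alpha, beta, q0) {
  beta / alpha + (q0 - beta / alpha) * exp(-alpha * t)
}
ou_var <- function(t, alpha, sigma) {
  sigma^2 / (2 * alpha) * (1 - exp(-2 * alpha * t))
}
ou_cov <- function(s, t, alpha, sigma) {   # s <= t
  exp(-alpha * (t - s)) * ou_var(s, alpha, sigma)
}

# Log joint Gaussian density of observations of the OU process at fixed
# times with iid N(0, sigma_y^2) measurement noise, q0 known.  Independent
# oracle for the Kalman prediction-error decomposition.
ou_joint_log_density <- function(alpha, beta, sigma, q0, times, values,
                                 sigma_y) {
  M <- length(times)
  mu <- ou_mean(times, alpha, beta, q0)
  C <- matrix(NA_real_, M, M)
  for (j in seq_len(M)) for (k in seq_len(M)) {
    s <- min(times[j], times[k]); t <- max(times[j], times[k])
    C[j, k] <- ou_cov(s, t, alpha, sigma)
  }
  C <- C + diag(sigma_y^2, M)
  L <- chol(C)
  z <- backsolve(L, values - mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(L))) - M / 2 * log(2 * pi)
}

# Brute-force bookkeeping oracle for the corrected likelihood estimate:
# carries every particle's uncorrected weight and its full inherited list of
# selection weights explicitly, then evaluates the corrected formula
# directly.  `script` is a list of elements of the form
#   list(op = "mult", factors = <N-vector>)  (weight evolution), or
#   list(op = "resample", v = <N-vector>, idx = <N-vector>) (selection).
likelihood_bookkeeping_oracle <- function(n, script) {
  w_uncorr <- rep(1, n)          # w_t(path) tracked per current particle
  v_inherited <- rep(1, n)       # prod over events of v at the inherited idx
  sum_v <- numeric(0)
  for (s in script) {
    if (s$op == "mult") {
      w_uncorr <- w_uncorr * s$factors
    } else {
      sum_v <- c(sum_v, sum(s$v))
      w_uncorr <- w_uncorr[s$idx]
      v_inherited <- v_inherited[s$idx] * s$v[s$idx]
    }
  }
  ell <- length(sum_v)
  (1 / n^(ell + 1)) * prod(sum_v) * sum(w_uncorr / v_inherited)
}

# The package-side representation of the same script: maintains corrected
# log-weights and the running log-sum-v history the way mtu_pf does.
likelihood_running_estimate <- function(n, script) {
  logw <- rep(0, n)              # corrected log-weights
  log_sum_v <- numeric(0)
  for (s in script) {
    if (s$op == "mult") {
      logw <- logw + log(s$factors)
    } else {
      log_sum_v <- c(log_sum_v, log(sum(s$v)))
      logw <- logw[s$idx] - log(s$v[s$idx])
    }
  }
  mtu_likelihood(logw, log_sum_v, n)
}

# Tiny two-observation MTU setup with supports away from t0, used by several
# mtu_pf tests.
toy_mtu_setup <- function(sigma_y = 0.2) {
  cfg <- motivating_config(intended_times = c(2, 4), sigma_y = sigma_y)
  dat <- list(values = c(2.6, 2.9))
  list(cfg = cfg,
       model = motivating_model(cfg),
       obs = motivating_observations(dat$values, cfg, sigma_y = sigma_y))
}
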