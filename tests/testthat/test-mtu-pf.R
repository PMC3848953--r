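test_that("partial-weight step accumulates Euler increments on the support", {
  # constant density 0.5 on [0, 2], no analytic cdf: pure Euler branch
  td <- time_density(pdf = function(t) ifelse(t >= 0 & t <= 2, 0.5, 0),
                     cdf = NULL, support = c(0, 2))
  up <- partial_weight_step(0, 0, log(2), td, t = 0, dt = 0.1)
  expect_equal(up$gamma_bar, 0.05)
  expect_equal(up$w_bar, 0.10)
  expect_equal(1 - up$gamma_bar + up$w_bar, 1.05)

  # below the support nothing changes
  td2 <- truncated_normal_time_density(2, 0.3, 1, 3)
  up2 <- partial_weight_step(0, c(0, 0), c(0, 0), td2, t = 0.2, dt = 0.1)
  expect_equal(up2$gamma_bar, 0)
  expect_equal(up2$w_bar, c(0, 0))
})

test_that("g identically 1 keeps the combined weight at 1 through the support", {
  td <- time_density(pdf = function(t) ifelse(t >= 0 & t <= 2, 0.5, 0),
                     cdf = NULL, support = c(0, 2))
  gb <- 0; wb <- rep(0, 3)
  for (t in seq(0, 1.9, by = 0.1)) {
    up <- partial_weight_step(gb, wb, rep(0, 3), td, t, 0.1)
    gb <- up$gamma_bar; wb <- up$w_bar
    expect_equal(combined_weight(gb, matrix(wb, ncol = 1)), rep(1, 3))
  }
})

test_that("combined weight is the corrected product of factors", {
  # M = 0 observations: weight is 1 / v_bar
  expect_equal(combined_weight(numeric(0), matrix(0, 2, 0),
                               log_v_bar = log(c(1, 4))), c(1, 0.25))
  expect_equal(combined_weight(c(0, 0), matrix(0, 1, 2)), 1)
  # factors (1.05, 0.9), v_bar = 3
  expect_equal(combined_weight(c(0.15, 0.2), cbind(0.2, 0.1),
                               log_v_bar = log(3)), 1.05 * 0.9 / 3)
  # zero factor short-circuits without poisoning others
  lw <- combined_weight(c(1, 0.2), cbind(c(0, 2), c(0.1, 0.1)), log = TRUE)
  expect_identical(lw[1], -Inf)
  expect_equal(lw[2], log(2 * 0.9))
})

test_that("predicted ESS matches the realized update", {
  s <- toy_mtu_setup()
  X <- matrix(c(2.55, 2.7), 2, 1)
  gb <- rep(0, 2); wb <- matrix(0, 2, 2)
  # dt too small to cross any mass: prediction equals current ESS
  expect_equal(predict_ess(X, gb, wb, rep(0, 2), s$obs, t = 0.5, dt = 1e-9),
               2)
  # identical particles: ESS stays N whatever dt
  Xeq <- matrix(2.6, 2, 1)
  expect_equal(predict_ess(Xeq, gb, wb, rep(0, 2), s$obs, t = 1.5, dt = 0.1),
               2)
  # hand-computed two-particle case inside the first support: the factor
  # becomes 1 - cdf(t+dt) + g * (mass crossed during the step)
  t <- 1.5; dt <- 0.1
  td <- s$obs[[1]]$time_density
  g <- exp(s$obs[[1]]$value_log_density(s$obs[[1]]$value, X, t))
  fac <- 1 - td$cdf(t + dt) + g * (td$cdf(t + dt) - td$cdf(t))
  expect_equal(predict_ess(X, gb, wb, rep(0, 2), s$obs, t, dt),
               ess(fac))
})

test_that("adaptive stepsize interpolates, halves and respects the floor", {
  N <- 100
  # unchanged ESS and benign prediction: dt_max
  expect_equal(adaptive_stepsize(N, N, N, 1e-6, 1e-2,
                                 predict = function(dt) N), 1e-2)
  # drop of N - 1: dt_min before any prediction
  expect_equal(adaptive_stepsize(1, N, N, 1e-6, 1e-2,
                                 predict = function(dt) N), 1e-6)
  # prediction always violating the 10% rule: floor returned
  expect_equal(adaptive_stepsize(N, N, N, 1e-6, 1e-2,
                                 predict = function(dt) 0), 1e-6)
  # halving stops as soon as the prediction is acceptable
  got <- adaptive_stepsize(N, N, N, 1e-6, 1e-2,
                           predict = function(dt) if (dt > 3e-3) 0 else N)
  expect_equal(got, 2.5e-3)
  # support boundaries cap the step
  expect_equal(adaptive_stepsize(N, N, N, 1e-6, 1e-2, cap = 1e-3,
                                 predict = function(dt) N), 1e-3)
})

test_that("corrected likelihood estimate equals the bookkeeping oracle", {
  # no resampling: mean of combined weights
  expect_equal(mtu_likelihood(log(c(0.5, 1.5, 1))), 1)
  # all weights 1, one resampling with v = 1: exactly 1
  expect_equal(mtu_likelihood(rep(0, 4), log_sum_v = log(4), n_particles = 4),
               1)
  # 3-particle, 2-resampling scripted traces vs the explicit oracle
  scripts <- list(
    list(list(op = "mult", factors = c(1.2, 0.4, 2.5)),
         list(op = "resample", v = c(1.2, 0.4, 2.5), idx = c(3L, 1L, 3L)),
         list(op = "mult", factors = c(0.9, 1.1, 0.3)),
         list(op = "resample", v = c(2, 1, 0.5), idx = c(1L, 1L, 2L)),
         list(op = "mult", factors = c(1.05, 0.95, 1))),
    list(list(op = "mult", factors = c(3, 1, 0.2)),
         list(op = "resample", v = c(0.5, 0.5, 1), idx = c(2L, 3L, 3L)),
         list(op = "resample", v = c(4, 1, 1), idx = c(1L, 1L, 3L))))
  for (sc in scripts) {
    expect_equal(likelihood_running_estimate(3, sc),
                 likelihood_bookkeeping_oracle(3, sc))
  }
})

test_that("MTU filter without observations keeps all weights equal", {
  m <- motivating_model()
  set.seed(4)
  tr <- mtu_pf(m, list(), n_particles = 30, t_end = 0.5, dt_max = 0.05,
               dt_min = 1e-6)
  expect_true(all(tr$ess == 30))
  expect_true(all(tr$loglik == 0))
})

test_that("combined weights stay 1 until the first support is entered", {
  s <- toy_mtu_setup()
  set.seed(8)
  tr <- mtu_pf(s$model, s$obs, n_particles = 40, t_end = 5.5,
               dt_max = 0.05, dt_min = 1e-6)
  before <- tr$times < 1 - 1e-9     # first support starts at 2 - 1 = 1
  expect_equal(tr$ess[before], rep(40, sum(before)))
  expect_equal(tr$loglik[before], rep(0, sum(before)))
  # support boundaries are grid points
  expect_true(all(c(1, 3, 5) %in% round(tr$times, 10)))
})

test_that("MTU traces are reproducible under a fixed seed", {
  s <- toy_mtu_setup()
  set.seed(21); tr1 <- mtu_pf(s$model, s$obs, n_particles = 60, t_end = 5.5,
                              dt_max = 0.05, dt_min = 1e-6)
  set.seed(21); tr2 <- mtu_pf(s$model, s$obs, n_particles = 60, t_end = 5.5,
                              dt_max = 0.05, dt_min = 1e-6)
  expect_identical(tr1$loglik, tr2$loglik)
  expect_identical(tr1$ess, tr2$ess)
  expect_identical(tr1$dt, tr2$dt)
})

test_that("likelihood estimate is insensitive to the resampling threshold", {
  # same data, with vs without resampling: estimates agree in expectation
  s <- toy_mtu_setup(sigma_y = 0.3)
  run <- function(seed, thr) {
    set.seed(seed)
    tr <- mtu_pf(s$model, s$obs, n_particles = 150, t_end = 5.5,
                 dt_max = 0.05, dt_min = 1e-6, resample_threshold = thr)
    tr$loglik[length(tr$loglik)]
  }
  with_rs <- vapply(1:60, run, numeric(1), thr = 75)
  without <- vapply(61:120, run, numeric(1), thr = 1e-9)
  # compare on the likelihood scale, where the estimator is unbiased
  z_with <- exp(with_rs); z_without <- exp(without)
  se <- sqrt(var(z_with) / 60 + var(z_without) / 60)
  expect_lt(abs(mean(z_with) - mean(z_without)), 3 * se)
})
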