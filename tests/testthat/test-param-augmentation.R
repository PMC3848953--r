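test_that("decay coefficients solve the two interpolation conditions", {
  ab <- decay_coefficients(0, 0.5, 2, 0.05)
  expect_equal(ab[["b_theta"]], -0.9249, tolerance = 1e-3)
  expect_equal(ab[["a_theta"]], 0.4277, tolerance = 1e-3)
  sig <- function(t) ab[["a_theta"]] / (t - ab[["b_theta"]])^2
  expect_equal(sig(0), 0.5)
  expect_equal(sig(2), 0.05)
  expect_lt(ab[["b_theta"]], 0)          # pole left of the horizon
  expect_error(decay_coefficients(0, 0.5, 2, 0.5), "decaying")
  expect_error(decay_coefficients(0, 0.5, 2, 0.7), "decaying")
  # generic property: both points reproduced for other choices
  for (pars in list(c(0, 1, 2, 0.1), c(1, 0.3, 4, 0.003))) {
    ab <- decay_coefficients(pars[1], pars[2], pars[3], pars[4])
    s <- function(t) ab[["a_theta"]] / (t - ab[["b_theta"]])^2
    expect_equal(s(pars[1]), pars[2])
    expect_equal(s(pars[3]), pars[4])
  }
})

test_that("the quadratic schedule decays with finite remaining variance", {
  d <- artificial_dynamics("geometric", t0 = 0, sigma0 = 0.5,
                           t1 = 2, sigma1 = 0.05)
  ts <- seq(0, 10, by = 0.5)
  expect_true(all(diff(d$sigma_of_t(ts)) < 0))
  tail_var <- integrate(function(t) d$sigma_of_t(t)^2, 0, Inf)$value
  expect_true(is.finite(tail_var))
})

test_that("parameter propagation uses exact positivity-preserving increments", {
  dyn0 <- list(artificial_dynamics("geometric", sigma_of_t = function(t) 0))
  expect_equal(propagate_parameters(c(1.3, 0.2), rep(dyn0, 2), 0, 1), c(1.3, 0.2))
  dyn <- list(artificial_dynamics("geometric", sigma_of_t = function(t) 0.5))
  expect_equal(propagate_parameters(1, dyn, 0, 1, z = matrix(0, 1, 1)),
               exp(-0.125))
  add <- list(artificial_dynamics("additive", sigma_of_t = function(t) 0.5))
  expect_equal(propagate_parameters(0, add, 0, 4, z = matrix(2, 1, 1)),
               0.5 * 2 * 2)
  # positivity preserved for extreme draws
  for (zv in c(-8, 8))
    expect_gt(propagate_parameters(1e-4, dyn, 0, 1,
                                   z = matrix(zv, 1, 1)), 0)
})

test_that("log-parameter variance accumulates the integrated schedule", {
  set.seed(6)
  d <- artificial_dynamics("geometric", a_theta = 5.43, b_theta = -3.29)
  dyn <- list(d)
  n <- 10000; dt <- 0.01; ts <- seq(0, 1 - dt, by = dt)
  th <- matrix(1, n, 1)
  for (t in ts) th <- propagate_parameters(th, dyn, t, dt)
  # exact variance of the simulated scheme: sum of per-step sigma^2 dt
  v_exact <- sum(d$sigma_of_t(ts)^2 * dt)
  v_hat <- var(log(th[, 1]))
  expect_lt(abs(v_hat - v_exact), 3 * v_exact * sqrt(2 / (n - 1)))
})

test_that("augmentation reproduces the base dynamics at frozen parameters", {
  cfg <- motivating_config(sigma = 0, sigma_q0 = 0)   # deterministic state
  frozen <- artificial_dynamics("geometric", sigma_of_t = function(t) 0)
  m <- motivating_estimation_model(cfg,
    prior_alpha = function(n) rep(1, n), prior_beta = function(n) rep(3, n),
    dynamics_alpha = frozen, dynamics_beta = frozen)
  set.seed(1)
  X <- m$sample_initial(5)
  for (t in seq(0, 1 - 0.01, by = 0.01)) X <- m$step_particles(X, t, 0.01)
  expect_equal(X[, "q"], rep(ou_mean(1, 1, 3, 1), 5), tolerance = 2e-2)
  expect_equal(X[, "alpha"], rep(1, 5))
  expect_equal(X[, "beta"], rep(3, 5))
})

test_that("name collisions between states and parameters are rejected", {
  expect_error(build_augmented_model(
    1, "alpha",
    drift = function(Q, Th, t) Q, diffusion = function(Q, Th, t) Q,
    sample_q0 = function(n) matrix(1, n, 1),
    priors = list(alpha = function(n) rep(1, n)),
    dynamics = list(alpha = artificial_dynamics("geometric"))),
    "collide")
})

test_that("the initial parameter cloud reproduces the prior", {
  m <- motivating_estimation_model()
  set.seed(31)
  X <- m$sample_initial(20000)
  # prior medians: alpha 2, beta 6 (log-normal)
  se_med <- 1.2533 * 1 / sqrt(20000)    # asymptotic se of a log-median
  expect_lt(abs(median(log(X[, "alpha"])) - log(2)), 3 * se_med)
  expect_lt(abs(median(log(X[, "beta"])) - log(6)), 3 * se_med)
})
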