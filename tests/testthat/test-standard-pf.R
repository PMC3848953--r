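test_that("ESS spans [1, N] with the documented boundary cases", {
  expect_equal(ess(rep(0.3, 10)), 10)
  expect_equal(ess(c(0, 0, 5, 0)), 1)
  expect_equal(ess(c(2, 1, 1)), 8 / 3)   # normalized (1/2, 1/4, 1/4)
  expect_error(ess(c(0, 0, 0)), "degeneracy")
  set.seed(5)
  for (i in 1:20) {
    w <- rexp(25)
    e <- ess(w)
    expect_gte(e, 1); expect_lte(e, 25)
    if (max(w) - min(w) > 1e-12) expect_lt(e, 25)
  }
})

test_that("resampling corrects weights and respects point masses", {
  set.seed(2)
  out <- resample(states = 1:4, weights = c(2, 1, 1, 4))
  expect_equal(out$weights, rep(1, 4))     # v = w: all corrected weights 1
  out <- resample(states = 1:3, weights = c(5, 1, 1),
                  selection_weights = c(1, 0, 0))
  expect_true(all(out$indices == 1L))
  expect_error(resample(1:3, c(1, 1, 1), selection_weights = c(0, 0, 0)),
               "degeneracy")
})

test_that("each scheme selects indices with the right marginal probabilities", {
  set.seed(11)
  v <- c(2, 1, 1)
  p <- v / sum(v)
  for (scheme in c("multinomial", "stratified", "systematic")) {
    idx <- replicate(3000, resample_indices(v, 3, scheme))
    freq <- tabulate(idx, 3) / length(idx)
    se <- sqrt(p * (1 - p) / length(idx))
    expect_true(all(abs(freq - p) < 3 * se + 1e-3), info = scheme)
  }
})

test_that("resampling preserves weighted expectations on average", {
  set.seed(12)
  x <- c(-1, 0.5, 2); w <- c(0.2, 1, 0.5)
  target <- sum(w * x) / sum(w)
  reps <- replicate(10000, {
    out <- resample(x, w, scheme = "multinomial")
    sum(out$weights * out$states) / sum(out$weights)
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - target), 3 * se)
})

test_that("likelihood ratio update reduces to the documented special cases", {
  expect_equal(likelihood_ratio_update(log(1), log(0.37)), log(0.37))
  g <- c(0.2, 0.5, 0.8)
  expect_equal(likelihood_ratio_update(rep(0, 3), log(g)), log(mean(g)))
  expect_equal(likelihood_ratio_update(log(c(2, 0)), log(c(0.5, 7))),
               log(0.5))
})

test_that("filter expectations are self-normalized weighted means", {
  expect_equal(filter_expectation(c(1, 2, 3), c(1, 5, 2), function(x) 7), 7)
  expect_equal(filter_expectation(c(1, 2, 3), c(1, 1, 1), function(x) x^2),
               mean(c(1, 4, 9)))
  expect_equal(filter_expectation(c(10, 20), c(1, 3),
                                  function(x) ifelse(x > 15, 4, 0)), 3)
})

test_that("weighted quantiles follow the cumulative-weight definition", {
  x <- c(3, 1, 2); w <- c(1, 1, 2)
  q <- weighted_quantile(x, w, c(0.25, 0.5, 1))
  expect_equal(unname(q), c(1, 2, 3))
})

test_that("standard filter with no data keeps ESS at N and log-likelihood 0", {
  m <- motivating_model()
  set.seed(1)
  tr <- standard_pf(m, list(), n_particles = 50, t_end = 1, dt = 0.1)
  expect_true(all(tr$ess == 50))
  expect_true(all(tr$loglik == 0))
})

test_that("standard filter traces are reproducible and hit measurement times", {
  cfg <- motivating_config()
  dat <- motivating_example_data()
  obs <- motivating_observations(dat$values, cfg, sigma_y = 0.5,
                                 uncertain_times = FALSE)
  m <- motivating_estimation_model(cfg)
  set.seed(9); tr1 <- standard_pf(m, obs, n_particles = 200, t_end = 5,
                                  dt = 0.013)
  set.seed(9); tr2 <- standard_pf(m, obs, n_particles = 200, t_end = 5,
                                  dt = 0.013)
  expect_identical(tr1$loglik, tr2$loglik)
  expect_identical(tr1$ess, tr2$ess)
  # measurement times are exact grid points even though 0.013 never hits them
  expect_true(all(dat$times %in% tr1$times))
})

test_that("total weight collapse aborts with a diagnostic trace", {
  m <- motivating_model()
  impossible <- observation(1, 0, function(y, X, t) rep(-Inf, nrow(X)),
                            fixed_time = 0.5)
  set.seed(1)
  err <- tryCatch(
    standard_pf(m, list(impossible), n_particles = 20, t_end = 1, dt = 0.1),
    error = identity)
  expect_match(conditionMessage(err), "degeneracy")
  expect_s3_class(err$trace, "filter_trace")
})
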