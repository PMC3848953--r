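test_that("drift and noise respect tracer mass balance", {
  set.seed(3)
  for (i in 1:10) {
    pars <- leucine_params(k01_c = runif(1, 0.1, 1), k12 = runif(1, 0.1, 1),
                           k13 = runif(1, 0.1, 1), k31 = runif(1, 0.1, 1),
                           k43 = runif(1, 0.1, 1))
    q <- runif(4, 0, 60)
    k01 <- runif(1, 0.1, 1)
    dd <- leucine_drift_diffusion(q, pars, k01)
    # deterministic mass balance: only the two outputs drain the system
    expect_equal(sum(dd$drift), -k01 * q[1] - pars$k112 * q[2])
    # noise mass balance: internal fluxes cancel columnwise
    expect_equal(colSums(dd$diffusion),
                 c(-k01 * pars$sigma_i[1], -pars$k112 * pars$sigma_i[2], 0, 0))
  }
  # closed system (outputs zeroed): drift and noise conserve mass exactly
  pars <- leucine_params()
  pars$k112 <- 0
  dd <- leucine_drift_diffusion(c(10, 5, 3, 1), pars, k01 = 0)
  expect_equal(sum(dd$drift), 0)
  expect_equal(colSums(dd$diffusion), rep(0, 4))
})

test_that("noiseless tracer dynamics match the matrix-exponential solution", {
  pars <- leucine_params(sigma_i = c(0, 0, 0, 0))
  K <- rbind(c(-(0.5 + 0.577 + 0.3), 0.5, 0.2, 0),
             c(0.5, -(0.01 + 0.5), 0, 0),
             c(0.3, 0, -(0.2 + 0.1), 0.01),
             c(0, 0, 0.1, -0.01))
  q0 <- c(50, 0, 0, 0)
  dt <- 1e-4
  q <- q0
  for (k in seq_len(round(0.5 / dt)))
    q <- q + leucine_drift_diffusion(q, pars, 0.577)$drift * dt
  exact <- drop(as.matrix(Matrix::expm(K * 0.5)) %*% q0)
  expect_equal(q, exact, tolerance = 1e-3)
})

test_that("steady-state tracee solves the stationary equations", {
  pars <- leucine_params(k12 = 0.5, U1 = 100)
  expect_equal(steady_state_Q1(pars, k01 = 0.577),
               51 / (0.577 * 0.51 + 0.005))
  # k11,2 = 0 limit: Q1 = U1 / k01
  p0 <- pars; p0$k112 <- 0
  expect_equal(steady_state_Q1(p0, k01 = 0.4), 100 / 0.4)
  # homogeneity in U1
  p2 <- leucine_params(k12 = 0.5, U1 = 300)
  expect_equal(steady_state_Q1(p2, 0.577), 3 * steady_state_Q1(pars, 0.577))
})

test_that("patient-level rates resolve group and random effect", {
  expect_equal(patient_k01("control", 1, 0.577, 0.346), 0.577)
  expect_equal(patient_k01("diabetes", exp(0), 0.577, 0.346), 0.346)
  expect_equal(patient_k01("diabetes", 1.2, 0.577, 0.3), 0.36)
  expect_error(patient_k01("other", 1, 0.5, 0.3), "group")
  expect_error(patient_k01("control", -1, 0.5, 0.3), "zeta")
})

test_that("population files round-trip and reject malformed records", {
  recs <- list(
    list(id = "c01", group = "control", u10 = 50.25,
         times = c(0.05, 0.1), values = c(0.21, 0.173)),
    list(id = "d01", group = "diabetes", u10 = 48,
         times = c(0.05, 0.1, 0.2), values = c(0.3, 0.25, 0.21)))
  f <- withr::local_tempfile()
  write_population_file(recs, f)
  expect_identical(read_population_file(f), recs)

  writeLines(c("p1,control,50", "0.1,0.2", "0.3", ""), f)
  expect_error(read_population_file(f), "mismatch")
  writeLines(c("p1,unknown,50", "0.1", "0.3", ""), f)
  expect_error(read_population_file(f), "group")
  writeLines(c("p1,control,50", "0.1,abc", "0.3,0.4", ""), f)
  expect_error(read_population_file(f), "non-numeric")
})

test_that("population model dimension is 4P + 7 + P", {
  one <- list(list(id = "a", group = "control", u10 = 50,
                   times = numeric(0), values = numeric(0)))
  pop1 <- build_population_model(one)
  expect_equal(pop1$model$dim, 4 + 7 + 1)
  expect_length(pop1$observations, 0)

  set.seed(2)
  recs <- generate_leucine_population(P_control = 2, P_diabetes = 1)
  pop <- build_population_model(recs)
  expect_equal(pop$model$dim, 4 * 3 + 7 + 3)
  expect_length(pop$observations, 3 * 8)
  dup <- c(recs, recs[1])
  expect_error(build_population_model(dup), "duplicate")
})

test_that("closed-system Euler steps conserve total tracer mass exactly", {
  # outputs zeroed via k01 = 0 (per-patient) and k112 = 0
  one <- list(list(id = "a", group = "control", u10 = 50,
                   times = numeric(0), values = numeric(0)))
  pars <- leucine_params()
  pars$k112 <- 0
  pop <- build_population_model(one, params = pars)
  set.seed(5)
  X <- pop$model$sample_initial(200)
  X[, "k01_c"] <- 0      # zero the output channel
  X[, "eta_a"] <- 0
  frozen <- X
  for (t in seq(0, 0.1, by = 1e-3)) frozen <- pop$model$step_particles(frozen, t, 1e-3)
  expect_equal(rowSums(frozen[, 1:4]), rowSums(X[, 1:4]), tolerance = 1e-10)
})

test_that("simulated ratio observations have the log-normal median", {
  set.seed(10)
  pars <- leucine_params()
  Q1 <- steady_state_Q1(pars, pars$k01_c)
  q1 <- 40
  y <- pars$p1 * q1 / Q1 * exp(rnorm(10000, 0, pars$sigma_y1))
  med <- pars$p1 * q1 / Q1
  expect_lt(abs(median(log(y)) - log(med)),
            3 * 1.2533 * pars$sigma_y1 / sqrt(10000))
})
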