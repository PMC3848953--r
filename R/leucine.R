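#' Parameters of the four-compartment plasma-leucine tracer model
#'
#' The leucine pool submodel: plasma leucine (compartment 1), an
#' intra-hepatic compartment (2) and two body protein pools (3, 4), probed by
#' a labelled-leucine bolus.  Fractional transfer coefficients are in 1/h,
#' masses in mg.  The constraints \eqn{k_{2,1} = k_{1,2}} and
#' \eqn{k_{3,4} = 0.1\,k_{4,3}} hold by construction;
#' \eqn{k_{11,2} = 0.01} 1/h is fixed for identifiability, the plasma
#' proportion \eqn{p_1 = 0.65} is fixed because it is not jointly
#' identifiable with \eqn{U_1}, the mass-conserving diffusion scales are
#' \eqn{\sigma_i = 3} and the log-scale observation noise is
#' \eqn{\sigma_{y_1} = 0.5}.
#'
#' @param k01_c,k01_d Group plasma degradation rates (control, diabetes), 1/h.
#' @param k12,k13,k31,k43 Transfer coefficients, 1/h.
#' @param U1 Constant tracee input into compartment 1, mg/h.
#' @param sigma_i Diffusion scales for the four Wiener channels.
#' @param sigma_y1 Log-normal observation noise sd.
#' @return A list of class `"leucine_params"` (including the derived `k21`,
#'   `k34` and the fixed `k112`, `p1`).
#' @export
leucine_params <- function(k01_c = 0.577, k01_d = 0.346,
                           k12 = 0.5, k13 = 0.2, k31 = 0.3, k43 = 0.1,
                           U1 = 100, sigma_i = c(3, 3, 3, 3),
                           sigma_y1 = 0.5) {
  rates <- c(k01_c = k01_c, k01_d = k01_d, k12 = k12, k13 = k13,
             k31 = k31, k43 = k43, U1 = U1)
  if (any(rates <= 0))
    stop("all rate parameters must be > 0: ",
         paste(names(rates)[rates <= 0], collapse = ", "))
  structure(list(k01_c = k01_c, k01_d = k01_d, k12 = k12, k13 = k13,
                 k31 = k31, k43 = k43, U1 = U1,
                 k21 = k12, k34 = 0.1 * k43, k112 = 0.01, p1 = 0.65,
                 sigma_i = sigma_i, sigma_y1 = sigma_y1),
            class = "leucine_params")
}

# Transfer matrix K for a given plasma degradation rate k01.
leucine_K <- function(params, k01) {
  with(params, rbind(
    c(-(k12 + k01 + k31), k12,            k13,          0),
    c(k12,                -(k112 + k12),  0,            0),
    c(k31,                0,              -(k13 + k43), 0.1 * k43),
    c(0,                  0,              k43,          -0.1 * k43)))
}

#' Drift and mass-conserving diffusion of the leucine tracer SDE
#'
#' Each flux between compartments perturbs donor mass as
#' \eqn{q_i\,dt + \sigma_i\,dW_i}, so internal fluxes conserve tracer mass
#' in the noise as well as the drift: the drift is \eqn{K q} and the
#' diffusion matrix is \eqn{K\,\mathrm{diag}(\sigma)} (column \eqn{i} is
#' \eqn{\sigma_i} times compartment \eqn{i}'s net flux-coefficient vector).
#' Column sums of the diffusion matrix are
#' \eqn{(-k_{0,1}\sigma_1, -k_{11,2}\sigma_2, 0, 0)} — only the two output
#' channels leak mass.
#'
#' @param q Tracer state 4-vector (mg).
#' @param params A [leucine_params()].
#' @param k01 Plasma degradation rate to use (1/h); patient-resolved via
#'   [patient_k01()], defaults to the control-group rate.
#' @return List with `drift` (4-vector, mg/h) and `diffusion` (4x4 matrix).
#' @export
leucine_drift_diffusion <- function(q, params, k01 = params$k01_c) {
  K <- leucine_K(params, k01)
  list(drift = drop(K %*% q),
       diffusion = K %*% diag(params$sigma_i))
}

#' Steady-state tracee mass in the plasma compartment
#'
#' The tracee system is assumed in steady state with constant input
#' \eqn{U_1}; solving the stationary equations for the plasma compartment
#' gives
#' \deqn{Q_1 = \frac{(k_{11,2} + k_{1,2})\,U_1}
#'       {k_{0,1}(k_{11,2} + k_{1,2}) + k_{11,2}\,k_{1,2}}.}
#'
#' @param params A [leucine_params()] (or anything with `k112`, `k12`, `U1`).
#' @param k01 Plasma degradation rate (1/h).
#' @return Steady-state plasma tracee mass \eqn{Q_1} (mg).
#' @export
steady_state_Q1 <- function(params, k01 = params$k01_c) {
  den <- k01 * (params$k112 + params$k12) + params$k112 * params$k12
  if (den <= 0) stop("steady-state denominator must be positive")
  (params$k112 + params$k12) * params$U1 / den
}

#' Patient-level plasma degradation rate
#'
#' Mixed-effects resolution of \eqn{k_{0,1}} for one patient:
#' \eqn{\zeta_p k_{0,1}^d} in the diabetes group, \eqn{\zeta_p k_{0,1}^c} in
#' the control group, with \eqn{\zeta_p = e^{\eta_p} > 0} the patient's
#' log-normal random effect.
#'
#' @param group `"control"` or `"diabetes"` (vectorized).
#' @param zeta_p Patient random factor(s), `> 0`.
#' @param k01_c,k01_d Group rates (1/h).
#' @return Patient rate(s) (1/h).
#' @export
patient_k01 <- function(group, zeta_p, k01_c, k01_d) {
  if (any(zeta_p <= 0)) stop("zeta_p must be > 0")
  if (!all(group %in% c("control", "diabetes")))
    stop("unknown group label: ",
         paste(setdiff(group, c("control", "diabetes")), collapse = ", "))
  zeta_p * ifelse(group == "diabetes", k01_d, k01_c)
}

#' Read / write a population data file
#'
#' Plain-text dialect for per-patient records, four lines per record:
#' a comma-separated header `id,group,u10` (group is `control` or
#' `diabetes`, `u10` the tracer bolus in mg), a comma-separated line of
#' nominal measurement times (h), a comma-separated line of measured
#' tracer/tracee ratios, and a blank separator line.
#'
#' @param path File path.
#' @return `read_population_file()` returns a list of patient records, each
#'   a list with `id`, `group`, `u10`, `times`, `values`;
#'   `write_population_file()` returns `path` invisibly.
#' @export
read_population_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  # drop trailing blanks, keep internal structure
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  records <- list()
  i <- 1L
  num <- function(s, ln) {
    v <- suppressWarnings(as.numeric(strsplit(s, ",")[[1]]))
    if (anyNA(v)) stop("non-numeric entry at line ", ln, ": ", s)
    v
  }
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (i + 2L > length(lines))
      stop("truncated record starting at line ", i)
    hdr <- trimws(strsplit(lines[i], ",")[[1]])
    if (length(hdr) != 3L)
      stop("expected `id,group,u10` at line ", i, ": ", lines[i])
    if (!hdr[2] %in% c("control", "diabetes"))
      stop("unknown group label at line ", i, ": ", hdr[2])
    u10 <- suppressWarnings(as.numeric(hdr[3]))
    if (is.na(u10)) stop("non-numeric initial value at line ", i)
    times <- num(lines[i + 1L], i + 1L)
    values <- num(lines[i + 2L], i + 2L)
    if (length(times) != length(values))
      stop("times/values length mismatch in record at line ", i)
    if (any(times < 0) || is.unsorted(times))
      stop("times must be nonnegative and nondecreasing (line ", i + 1L, ")")
    records[[length(records) + 1L]] <-
      list(id = hdr[1], group = hdr[2], u10 = u10,
           times = times, values = values)
    i <- i + 3L
  }
  records
}

#' @rdname read_population_file
#' @param records List of patient records.
#' @export
write_population_file <- function(records, path) {
  fmt <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                  scientific = FALSE), collapse = ",")
  lines <- unlist(lapply(records, function(r)
    c(paste(r$id, r$group, format(r$u10, digits = 17, trim = TRUE,
                                  scientific = FALSE), sep = ","),
      fmt(r$times), fmt(r$values), "")))
  writeLines(lines, path)
  invisible(path)
}

#' Augmented population model for the leucine study
#'
#' Builds one state-space model coupling all patients through the shared
#' parameters: per patient the four tracer compartments (initialized at
#' \eqn{(u_{1,0}, 0, 0, 0)}), then the seven shared positive parameters
#' \eqn{(k_{0,1}^c, k_{0,1}^d, k_{1,2}, k_{1,3}, k_{3,1}, k_{4,3}, U_1)}
#' with log-normal priors (LogN(0,1), except \eqn{U_1 \sim}
#' LogN(log 100, 1)) and geometric artificial noise, then one
#' \eqn{\eta_p \sim N(0, 0.5^2)} per patient with additive artificial noise.
#' Dimension: `4 P + 7 + P`.  Observation value densities are the log-normal
#' tracer/tracee ratio model with each particle's own steady-state
#' \eqn{Q_1}; time densities are truncated normals with sd `time_sd`
#' truncated at `time_halfwidth` around the nominal times (clipped at `t0`).
#'
#' @param records Patient records as from [read_population_file()];
#'   duplicate ids are an error.
#' @param params A [leucine_params()] supplying the fixed constants
#'   (`k112`, `p1`, `sigma_i`, `sigma_y1`); the free parameters come from
#'   the priors.
#' @param t0 Initial time (h).
#' @param time_sd,time_halfwidth Measurement-time density parameters (h).
#' @param sigma_eta Prior sd of the patient random effects.
#' @param decay_interp Interpolation points `(t0, sigma0, t1, sigma1)` for
#'   the shared parameters' artificial-noise schedule; the `eta` schedule
#'   uses twice `sigma0`/`sigma1`.
#' @return List with `model` (a [state_space_model()]) and `observations`.
#' @export
build_population_model <- function(records, params = leucine_params(),
                                   t0 = 0, time_sd = 0.001,
                                   time_halfwidth = 0.01,
                                   sigma_eta = 0.5,
                                   decay_interp = c(0, 0.5, 2, 0.05)) {
  P <- length(records)
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate patient ids")
  groups <- vapply(records, `[[`, character(1), "group")
  shared <- c("k01_c", "k01_d", "k12", "k13", "k31", "k43", "U1")
  qn <- as.vector(t(outer(ids, paste0("q", 1:4),
                          function(i, q) paste0(q, "_", i))))
  nm <- c(qn, shared, paste0("eta_", ids))
  dim <- 4 * P + 7 + P
  si <- params$sigma_i; k112 <- params$k112
  qi <- function(p) (p - 1) * 4 + 1:4
  th0 <- 4 * P
  et0 <- 4 * P + 7
  dyn_g <- artificial_dynamics("geometric", t0 = decay_interp[1],
                               sigma0 = decay_interp[2],
                               t1 = decay_interp[3], sigma1 = decay_interp[4])
  dyn_a <- artificial_dynamics("additive", t0 = decay_interp[1],
                               sigma0 = 2 * decay_interp[2],
                               t1 = decay_interp[3],
                               sigma1 = 2 * decay_interp[4])
  dynamics <- c(rep(list(dyn_g), 7), rep(list(dyn_a), P))

  step <- function(X, t, dt) {
    N <- nrow(X)
    k12 <- X[, th0 + 3]; k13 <- X[, th0 + 4]
    k31 <- X[, th0 + 5]; k43 <- X[, th0 + 6]
    sq <- sqrt(dt)
    for (p in seq_len(P)) {
      k01p <- exp(X[, et0 + p]) *
        X[, th0 + if (groups[p] == "diabetes") 2 else 1]
      cols <- qi(p)
      q1 <- X[, cols[1]]; q2 <- X[, cols[2]]
      q3 <- X[, cols[3]]; q4 <- X[, cols[4]]
      z1 <- stats::rnorm(N); z2 <- stats::rnorm(N)
      z3 <- stats::rnorm(N); z4 <- stats::rnorm(N)
      c1 <- k12 + k01p + k31; c2 <- k112 + k12; c3 <- k13 + k43
      X[, cols[1]] <- q1 + (-c1 * q1 + k12 * q2 + k13 * q3) * dt +
        sq * (-c1 * si[1] * z1 + k12 * si[2] * z2 + k13 * si[3] * z3)
      X[, cols[2]] <- q2 + (k12 * q1 - c2 * q2) * dt +
        sq * (k12 * si[1] * z1 - c2 * si[2] * z2)
      X[, cols[3]] <- q3 + (k31 * q1 - c3 * q3 + 0.1 * k43 * q4) * dt +
        sq * (k31 * si[1] * z1 - c3 * si[3] * z3 + 0.1 * k43 * si[4] * z4)
      X[, cols[4]] <- q4 + (k43 * q3 - 0.1 * k43 * q4) * dt +
        sq * (k43 * si[3] * z3 - 0.1 * k43 * si[4] * z4)
    }
    Th <- X[, th0 + seq_len(7 + P), drop = FALSE]
    X[, th0 + seq_len(7 + P)] <- propagate_parameters(Th, dynamics, t, dt)
    X
  }

  model <- state_space_model(
    dim = dim,
    drift = function(x, t) {
      out <- numeric(dim)
      for (p in seq_len(P)) {
        k01p <- exp(x[et0 + p]) *
          x[th0 + if (groups[p] == "diabetes") 2 else 1]
        pars <- leucine_params(k01_c = x[th0 + 1], k01_d = x[th0 + 2],
                               k12 = x[th0 + 3], k13 = x[th0 + 4],
                               k31 = x[th0 + 5], k43 = x[th0 + 6],
                               U1 = x[th0 + 7],
                               sigma_i = si, sigma_y1 = params$sigma_y1)
        out[qi(p)] <- leucine_drift_diffusion(x[qi(p)], pars, k01p)$drift
      }
      out
    },
    diffusion = function(x, t) {
      B <- matrix(0, dim, 4 * P)
      for (p in seq_len(P)) {
        k01p <- exp(x[et0 + p]) *
          x[th0 + if (groups[p] == "diabetes") 2 else 1]
        pars <- leucine_params(k01_c = x[th0 + 1], k01_d = x[th0 + 2],
                               k12 = x[th0 + 3], k13 = x[th0 + 4],
                               k31 = x[th0 + 5], k43 = x[th0 + 6],
                               U1 = x[th0 + 7],
                               sigma_i = si, sigma_y1 = params$sigma_y1)
        B[qi(p), (p - 1) * 4 + 1:4] <-
          leucine_drift_diffusion(x[qi(p)], pars, k01p)$diffusion
      }
      B
    },
    sample_initial = function(n) {
      X <- matrix(0, n, dim)
      for (p in seq_len(P)) X[, qi(p)[1]] <- records[[p]]$u10
      X[, th0 + 1:6] <- stats::rlnorm(6 * n, 0, 1)
      X[, th0 + 7] <- stats::rlnorm(n, log(100), 1)
      X[, et0 + seq_len(P)] <- stats::rnorm(P * n, 0, sigma_eta)
      X
    },
    step_particles = step,
    names = nm)

  observations <- list()
  jj <- 0L
  p1 <- params$p1; sy <- params$sigma_y1
  for (p in seq_len(P)) {
    r <- records[[p]]
    gcol <- th0 + if (groups[p] == "diabetes") 2 else 1
    q1col <- qi(p)[1]; ecol <- et0 + p
    for (m in seq_along(r$times)) {
      jj <- jj + 1L
      nominal <- r$times[m]
      local({
        y <- r$values[m]; q1c <- q1col; gc <- gcol; ec <- ecol
        observations[[jj]] <<- observation(
          index = jj, value = y,
          value_log_density = function(y, X, t) {
            k01p <- exp(X[, ec]) * X[, gc]
            k12v <- X[, th0 + 3]; U1v <- X[, th0 + 7]
            den <- k01p * (k112 + k12v) + k112 * k12v
            Q1 <- (k112 + k12v) * U1v / den
            lognormal_ratio_log_density(y, X[, q1c], Q1, p1, sy)
          },
          time_density = truncated_normal_time_density(
            nominal, time_sd,
            lo = max(t0, nominal - time_halfwidth),
            hi = nominal + time_halfwidth))
      })
    }
  }
  list(model = model, observations = observations)
}
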