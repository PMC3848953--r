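#' Decay coefficients for time-decaying artificial parameter noise
#'
#' Bayesian parameter estimation by state augmentation needs the parameters
#' to carry small artificial stochastic dynamics whose diffusion decays over
#' time, here the quadratic schedule
#' \eqn{\sigma_\theta(t) = a_\theta / (t - b_\theta)^2}.  The coefficients are
#' fixed by two interpolation points \eqn{(t_0, \sigma_0)} and
#' \eqn{(t_1, \sigma_1)} with \eqn{\sigma_1 < \sigma_0}: with
#' \eqn{r = \sqrt{\sigma_0/\sigma_1}},
#' \deqn{b = t_0 + (t_1 - t_0)/(1 - r) \;(< t_0), \qquad
#'       a = \sigma_0\,(t_0 - b)^2.}
#'
#' @param t0,sigma0 First interpolation point (h, diffusion value).
#' @param t1,sigma1 Second interpolation point, `t1 > t0`,
#'   `0 < sigma1 < sigma0`.
#' @return Named numeric vector `c(a_theta, b_theta)`.
#' @export
decay_coefficients <- function(t0, sigma0, t1, sigma1) {
  stopifnot(t1 > t0, sigma0 > 0)
  if (!(sigma1 > 0 && sigma1 < sigma0))
    stop("need 0 < sigma1 < sigma0 for a decaying schedule")
  r <- sqrt(sigma0 / sigma1)
  b <- t0 + (t1 - t0) / (1 - r)
  c(a_theta = sigma0 * (t0 - b)^2, b_theta = b)
}

#' Artificial parameter dynamics
#'
#' Describes the artificial noise attached to one augmented parameter:
#' `"geometric"` for positive parameters
#' (\eqn{d\theta = \theta\,\sigma_\theta(t)\,dW}), `"additive"` for
#' real-valued ones (\eqn{d\theta = \sigma_\theta(t)\,dW}), with the
#' quadratic decay schedule \eqn{\sigma_\theta(t) = a_\theta/(t-b_\theta)^2}.
#' Alternatively pass interpolation points via `t0, sigma0, t1, sigma1`
#' (see [decay_coefficients()]), an arbitrary `sigma_of_t` function, or
#' nothing at all for frozen parameters (\eqn{\sigma_\theta \equiv 0}).
#'
#' @param kind `"geometric"` or `"additive"`.
#' @param a_theta,b_theta Schedule coefficients (`b_theta < t0` makes the
#'   schedule strictly decreasing on the horizon).
#' @param t0,sigma0,t1,sigma1 Interpolation points, used when `a_theta` is
#'   missing.
#' @param sigma_of_t Explicit diffusion schedule function of time.
#' @return An object of class `"artificial_dynamics"`.
#' @export
artificial_dynamics <- function(kind = c("geometric", "additive"),
                                a_theta = NULL, b_theta = NULL,
                                t0 = NULL, sigma0 = NULL,
                                t1 = NULL, sigma1 = NULL,
                                sigma_of_t = NULL) {
  kind <- match.arg(kind)
  if (is.null(sigma_of_t)) {
    if (is.null(a_theta) && !is.null(t0)) {
      ab <- decay_coefficients(t0, sigma0, t1, sigma1)
      a_theta <- ab[["a_theta"]]; b_theta <- ab[["b_theta"]]
    }
    sigma_of_t <- if (is.null(a_theta)) function(t) 0 else {
      force(a_theta); force(b_theta)
      function(t) a_theta / (t - b_theta)^2
    }
  }
  structure(list(kind = kind, a_theta = a_theta, b_theta = b_theta,
                 sigma_of_t = sigma_of_t),
            class = "artificial_dynamics")
}

#' Propagate augmented parameters by one artificial-noise step
#'
#' Geometric parameters use the exact geometric-Brownian increment
#' \eqn{\theta \exp(\sigma\sqrt{\Delta t}\,z - \sigma^2 \Delta t / 2)}
#' (positivity is preserved for every draw, unlike an Euler step), additive
#' parameters use \eqn{\theta + \sigma \sqrt{\Delta t}\, z}, with
#' \eqn{\sigma = \sigma_\theta(t)} frozen over the step.
#'
#' @param theta `N x p` matrix (or `p`-vector) of parameter coordinates.
#' @param dynamics List of `p` [artificial_dynamics()] objects, one per
#'   column.
#' @param t Current time (h).
#' @param dt Stepsize (h), `> 0`.
#' @param z Optional `N x p` matrix of standard-normal draws (drawn from the
#'   global RNG when missing).
#' @return Matrix (or vector) of propagated parameters.
#' @export
propagate_parameters <- function(theta, dynamics, t, dt, z = NULL) {
  stopifnot(dt > 0)
  vec <- is.null(dim(theta))
  Th <- if (vec) matrix(theta, nrow = 1) else theta
  stopifnot(ncol(Th) == length(dynamics))
  if (is.null(z)) z <- matrix(stats::rnorm(length(Th)), nrow(Th), ncol(Th))
  for (k in seq_along(dynamics)) {
    s <- dynamics[[k]]$sigma_of_t(t)
    if (s == 0) next
    Th[, k] <- if (dynamics[[k]]$kind == "geometric")
      Th[, k] * exp(s * sqrt(dt) * z[, k] - s^2 * dt / 2)
    else
      Th[, k] + s * sqrt(dt) * z[, k]
  }
  if (vec) drop(Th) else Th
}

#' Augment a parameterized model with artificial parameter dynamics
#'
#' Builds a [state_space_model()] over the concatenated vector
#' `(q, theta)` in which the dynamic states follow the base drift/diffusion
#' evaluated at each particle's own parameter coordinates, and the parameter
#' coordinates follow their [artificial_dynamics()].  Used for Bayesian
#' parameter estimation: parameters are sampled from their priors at the
#' initial time and then filtered like states.
#'
#' @param state_dim Dimension of the dynamic state block `q`.
#' @param state_names Names of the `q` coordinates.
#' @param drift Vectorized function `(Q, Theta, t)` with `Q` an
#'   `N x state_dim` matrix and `Theta` an `N x p` matrix, returning the
#'   `N x state_dim` drift.
#' @param diffusion Vectorized function `(Q, Theta, t)` returning the
#'   `N x state_dim` per-coordinate (diagonal) diffusion; ignored when
#'   `state_noise` is given.
#' @param sample_q0 Function `(n)` returning `n x state_dim` initial states.
#' @param priors Named list of prior samplers `function(n)`, one per
#'   parameter; the names become coordinate names and must not collide with
#'   `state_names`.
#' @param dynamics Named list of [artificial_dynamics()] matching `priors`.
#' @param state_noise Optional function `(Q, Theta, t, dt)` returning the
#'   full `N x state_dim` stochastic increment (already scaled by
#'   `sqrt(dt)`), for models with non-diagonal mass-conserving noise.
#' @return A [state_space_model()] of dimension `state_dim + length(priors)`.
#' @export
build_augmented_model <- function(state_dim, state_names, drift, diffusion,
                                  sample_q0, priors, dynamics,
                                  state_noise = NULL) {
  stopifnot(length(priors) == length(dynamics),
            !is.null(names(priors)),
            all(names(priors) == names(dynamics)))
  if (any(names(priors) %in% state_names))
    stop("parameter names collide with state names: ",
         paste(intersect(names(priors), state_names), collapse = ", "))
  p <- length(priors)
  dq <- state_dim
  qi <- seq_len(dq); ti <- dq + seq_len(p)
  step <- function(X, t, dt) {
    Q <- X[, qi, drop = FALSE]; Th <- X[, ti, drop = FALSE]
    incr <- if (is.null(state_noise)) {
      B <- diffusion(Q, Th, t)
      sqrt(dt) * B * matrix(stats::rnorm(length(Q)), nrow(Q), dq)
    } else state_noise(Q, Th, t, dt)
    Qn <- Q + drift(Q, Th, t) * dt + incr
    cbind(Qn, propagate_parameters(Th, dynamics, t, dt))
  }
  state_space_model(
    dim = dq + p,
    drift = function(x, t) {
      Q <- matrix(x[qi], 1); Th <- matrix(x[ti], 1)
      c(drop(drift(Q, Th, t)), rep(0, p))   # parameter SDEs are driftless
    },
    diffusion = function(x, t) {
      Q <- matrix(x[qi], 1); Th <- matrix(x[ti], 1)
      s_par <- vapply(seq_len(p), function(k) {
        s <- dynamics[[k]]$sigma_of_t(t)
        if (dynamics[[k]]$kind == "geometric") s * x[ti[k]] else s
      }, numeric(1))
      c(drop(diffusion(Q, Th, t)), s_par)
    },
    sample_initial = function(n) {
      Th <- vapply(priors, function(pr) pr(n), numeric(n))
      if (n == 1L) Th <- matrix(Th, 1)
      cbind(sample_q0(n), Th)
    },
    step_particles = step,
    names = c(state_names, names(priors)))
}
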