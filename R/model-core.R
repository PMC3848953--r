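#' Continuous-time state-space model defined by an Ito SDE
#'
#' Bundles the drift \eqn{a(x,t)}, diffusion \eqn{B(x,t)} and initial-state
#' sampler of a continuous-time Markov process
#' \deqn{dX_t = a(X_t, t)\,dt + B(X_t, t)\,dW_t}
#' together with optional fast vectorized propagation across a particle cloud
#' and an optional importance-sampling proposal kernel.  All times are in
#' hours.
#'
#' @param dim State dimension (positive integer).
#' @param drift Function `(x, t)` returning the drift vector for a single
#'   state vector `x` (units: state-units per hour).
#' @param diffusion Function `(x, t)` returning either a scalar, a vector of
#'   per-coordinate diffusions (diagonal case), or a `dim x m` matrix applied
#'   to an `m`-dimensional Wiener increment (units: state-units per sqrt-hour).
#' @param sample_initial Function `(n)` returning an `n x dim` matrix of
#'   i.i.d. draws from the initial distribution.
#' @param step_particles Optional function `(X, t, dt)` advancing an
#'   `N x dim` matrix of particle states by one Euler--Maruyama step (or an
#'   exact scheme for sub-blocks, e.g. geometric parameter noise).  When
#'   `NULL`, a row-wise default built on [euler_maruyama_step()] is used;
#'   supply a vectorized version for large particle counts.
#' @param proposal Optional [proposal_kernel()]. `NULL` means sampling from
#'   the model kernel itself (all importance ratios are 1).
#' @param names Optional character vector of coordinate names (length `dim`).
#'
#' @return An object of class `"ssm"`.
#' @seealso [euler_maruyama_step()], [simulate_path()], [build_augmented_model()]
#' @export
state_space_model <- function(dim, drift, diffusion, sample_initial,
                              step_particles = NULL, proposal = NULL,
                              names = NULL) {
  stopifnot(is.numeric(dim), length(dim) == 1L, dim >= 1, dim == round(dim),
            is.function(drift), is.function(diffusion),
            is.function(sample_initial))
  if (!is.null(names) && length(names) != dim)
    stop("`names` must have length `dim`")
  coord_names <- names %||% paste0("x", seq_len(dim))
  model <- structure(
    list(dim = as.integer(dim), drift = drift, diffusion = diffusion,
         sample_initial = function(n) {
           X <- sample_initial(n)
           colnames(X) <- coord_names
           X
         },
         proposal = proposal, names = coord_names),
    class = "ssm")
  model$step_particles <- step_particles %||% default_step_particles(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ssm <- function(x, ...) {
  cat("<state-space model>  dim =", x$dim,
      " coords:", paste(x$names, collapse = ", "), "\n")
  cat("  proposal:", if (is.null(x$proposal)) "model kernel (prior)"
      else "custom", "\n")
  invisible(x)
}

# Row-wise fallback propagation; adequate for small clouds and tests.
default_step_particles <- function(model) {
  force(model)
  function(X, t, dt) {
    X <- as.matrix(X)
    for (i in seq_len(nrow(X))) {
      B <- model$diffusion(X[i, ], t)
      m <- if (is.matrix(B)) ncol(B) else length(X[i, ])
      X[i, ] <- euler_maruyama_step(X[i, ], model, t, dt,
                                    noise = stats::rnorm(m))
    }
    X
  }
}

#' One Euler--Maruyama step
#'
#' Advances a single state vector by
#' \eqn{x + a(x,t)\,\Delta t + B(x,t)\,\sqrt{\Delta t}\,\eta}
#' with a supplied standard-normal vector \eqn{\eta}.
#'
#' @param state Numeric state vector.
#' @param model A [state_space_model()].
#' @param t Current time (h).
#' @param dt Stepsize (h), strictly positive.
#' @param noise Standard-normal vector with the dimension of the driving
#'   Wiener process (`ncol` of the diffusion matrix, or the state dimension
#'   for scalar/diagonal diffusion).
#' @return The advanced state vector.
#' @export
euler_maruyama_step <- function(state, model, t, dt, noise) {
  stopifnot(dt > 0)
  a <- model$drift(state, t)
  B <- model$diffusion(state, t)
  if (!all(is.finite(a)))
    stop("non-finite drift at t = ", t)
  if (!all(is.finite(B)))
    stop("non-finite diffusion at t = ", t)
  incr <- if (is.matrix(B)) {
    stopifnot(length(noise) == ncol(B))
    drop(B %*% noise)
  } else {
    # scalar or diagonal diffusion
    stopifnot(length(noise) == length(state))
    B * noise
  }
  state + a * dt + sqrt(dt) * incr
}

#' Simulate a state path on a time grid
#'
#' Draws an initial state and applies [euler_maruyama_step()] along a strictly
#' increasing time grid.
#'
#' @param model A [state_space_model()].
#' @param t_grid Strictly increasing numeric vector of times (h), starting at
#'   the initial time.
#' @return A `length(t_grid) x dim` matrix; row `k` is the state at
#'   `t_grid[k]`. Column names are the model's coordinate names.
#' @export
simulate_path <- function(model, t_grid) {
  if (length(t_grid) < 1L || any(diff(t_grid) <= 0))
    stop("`t_grid` must be non-empty and strictly increasing")
  path <- matrix(NA_real_, length(t_grid), model$dim,
                 dimnames = list(NULL, model$names))
  path[1L, ] <- model$sample_initial(1L)
  if (length(t_grid) > 1L) {
    for (k in 2L:length(t_grid)) {
      B <- model$diffusion(path[k - 1L, ], t_grid[k - 1L])
      m <- if (is.matrix(B)) ncol(B) else model$dim
      path[k, ] <- euler_maruyama_step(path[k - 1L, ], model,
                                       t_grid[k - 1L],
                                       t_grid[k] - t_grid[k - 1L],
                                       noise = stats::rnorm(m))
    }
  }
  path
}

#' Importance-sampling proposal kernel
#'
#' Contract for sampling particle transitions from a proposal process
#' instead of the model kernel, with pointwise-computable Radon--Nikodym
#' log-ratios (log of the model-to-proposal transition density ratio).
#' When the proposal coincides with the model kernel both log-ratios are
#' identically zero; states outside the proposal's support have log-ratio
#' `-Inf` by convention.
#'
#' @param sample_step Function `(state, t_from, t_to)` returning a proposed
#'   state at `t_to`.
#' @param log_density_ratio Function `(state_to, state_from, t_from, t_to)`
#'   returning the transition log-ratio.
#' @param initial_log_ratio Function `(state)` returning the initial-time
#'   log-ratio.
#' @return An object of class `"proposal_kernel"`.
#' @export
proposal_kernel <- function(sample_step, log_density_ratio,
                            initial_log_ratio = function(state) 0) {
  structure(list(sample_step = sample_step,
                 log_density_ratio = log_density_ratio,
                 initial_log_ratio = initial_log_ratio),
            class = "proposal_kernel")
}

#' Transition log-ratio of a proposal kernel
#'
#' Evaluates the log Radon--Nikodym derivative of the model transition kernel
#' with respect to the proposal kernel. For the default (prior) proposal,
#' i.e. `kernel = NULL`, this is identically 0.
#'
#' @param kernel A [proposal_kernel()] or `NULL` for the prior proposal.
#' @param state_to,state_from States at `t_to` and `t_from`.
#' @param t_from,t_to Times with `t_to > t_from`.
#' @return A finite log-ratio, or `-Inf` outside the proposal support.
#' @export
transition_log_ratio <- function(kernel, state_to, state_from, t_from, t_to) {
  stopifnot(t_to > t_from)
  if (is.null(kernel)) return(0)
  kernel$log_density_ratio(state_to, state_from, t_from, t_to)
}
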