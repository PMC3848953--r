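#' Filter trace
#'
#' Container for the output of [standard_pf()] and [mtu_pf()]: the time grid,
#' the ESS sequence, the cumulative log-likelihood estimate, accepted
#' stepsizes (MTU only), thinned weighted quantiles of tracked coordinates,
#' the resampling-event log, and (in memory only) the final weighted particle
#' cloud.
#'
#' @param times Nondecreasing numeric vector of grid times (h).
#' @param ess ESS at each grid time, in `[1, N]`.
#' @param loglik Cumulative log-likelihood estimate at each grid time.
#' @param dt Accepted stepsizes (MTU) or `NULL` (standard filter).
#' @param quantile_times Times at which quantiles were recorded.
#' @param quantiles `R x K x 5` array of weighted quantiles
#'   (0.025, 0.25, 0.5, 0.75, 0.975) for `K` tracked coordinates, or `NULL`.
#' @param events List of one-row data frames (`time`, `ess_before`,
#'   `ess_after`, `log_sum_v`), one per resampling event.
#' @param n_particles Particle count `N`.
#' @param final Optional list with the final `states`, `log_weights` (and for
#'   MTU the per-event `log_sum_v`); not serialized by [write_trace()].
#' @param means Optional matrix of weighted posterior means (one row per grid
#'   time, one column per tracked coordinate).
#' @return An object of class `"filter_trace"`.
#' @export
filter_trace <- function(times, ess, loglik, dt = NULL,
                         quantile_times = NULL, quantiles = NULL,
                         events = list(), n_particles = NA_integer_,
                         final = NULL, means = NULL) {
  stopifnot(length(times) == length(ess), length(times) == length(loglik))
  structure(list(times = times, ess = ess, loglik = loglik, dt = dt,
                 means = means,
                 quantile_times = quantile_times, quantiles = quantiles,
                 events = if (length(events)) do.call(rbind, events) else
                   data.frame(time = numeric(0), ess_before = numeric(0),
                              ess_after = numeric(0), log_sum_v = numeric(0)),
                 n_particles = n_particles, final = final),
            class = "filter_trace")
}

#' @export
print.filter_trace <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<filter trace>  %d steps on [%g, %g], N = %s\n",
              n - 1L, x$times[1], x$times[n],
              format(x$n_particles)))
  cat(sprintf("  final log-likelihood %.4f | min ESS %.1f | %d resampling%s\n",
              x$loglik[n], min(x$ess), nrow(x$events),
              if (nrow(x$events) == 1) "" else "s"))
  invisible(x)
}

#' Final weighted parameter/state summary of a trace
#'
#' Weighted empirical quantiles of the final particle cloud — the package's
#' parameter estimates are the `q0.5` column (weighted medians).
#'
#' @param trace A [filter_trace()] whose in-memory `final` cloud is present.
#' @param coords Coordinate indices or names (default: all).
#' @param probs Quantile probabilities.
#' @return Data frame, one row per coordinate.
#' @export
final_estimates <- function(trace, coords = NULL,
                            probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  if (is.null(trace$final))
    stop("trace carries no final particle cloud (was it read from disk?)")
  X <- trace$final$states
  w <- exp(trace$final$log_weights - max(trace$final$log_weights))
  if (is.null(coords)) coords <- seq_len(ncol(X))
  if (is.character(coords)) coords <- match(coords, colnames(X))
  out <- t(vapply(coords, function(j) weighted_quantile(X[, j], w, probs),
                  numeric(length(probs))))
  data.frame(coord = colnames(X)[coords] %||% paste0("x", coords), out,
             row.names = NULL, check.names = FALSE)
}

#' Write / read a filter trace as CSV
#'
#' The trace is serialized at full precision into a single CSV file: one row
#' per grid time with columns `time`, `ess`, `loglik`, `dt` and, at record
#' times, `<coord>_q<prob>` quantile columns; the resampling-event log is
#' preserved in `#`-prefixed header lines.  `read_trace()` restores
#' everything except the in-memory final cloud.
#'
#' @param trace A [filter_trace()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   [filter_trace()].
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time = trace$times, ess = trace$ess,
                   loglik = trace$loglik,
                   dt = if (is.null(trace$dt))
                     rep(NA_real_, length(trace$times)) else trace$dt)
  if (!is.null(trace$means)) {
    mn <- as.matrix(trace$means)
    colnames(mn) <- paste0("mean_", colnames(trace$means) %||%
                             paste0("x", seq_len(ncol(mn))))
    df <- cbind(df, mn)
  }
  if (!is.null(trace$quantiles)) {
    K <- dim(trace$quantiles)[2]; P <- dim(trace$quantiles)[3]
    qn <- outer(dimnames(trace$quantiles)[[2]],
                dimnames(trace$quantiles)[[3]], paste, sep = "_")
    qm <- matrix(NA_real_, nrow(df), K * P, dimnames = list(NULL, as.vector(qn)))
    ridx <- vapply(trace$quantile_times,
                   function(tm) which.min(abs(df$time - tm)), integer(1))
    for (r in seq_along(ridx))
      qm[ridx[r], ] <- as.vector(trace$quantiles[r, , ])
    df <- cbind(df, qm)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_particles %s", format(trace$n_particles)), con)
  if (nrow(trace$events))
    writeLines(sprintf("# resample %s %s %s %s",
                       format(trace$events$time, digits = 17),
                       format(trace$events$ess_before, digits = 17),
                       format(trace$events$ess_after, digits = 17),
                       format(trace$events$log_sum_v, digits = 17)), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- grep("^#", readLines(path), value = TRUE)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!all(c("time", "ess", "loglik", "dt") %in% names(df)))
    stop("not a filter-trace file (schema mismatch): ", path)
  np <- sub("^# n_particles ", "", grep("^# n_particles", hdr, value = TRUE))
  ev <- grep("^# resample ", hdr, value = TRUE)
  events <- lapply(ev, function(l) {
    f <- as.numeric(strsplit(sub("^# resample ", "", l), " +")[[1]])
    data.frame(time = f[1], ess_before = f[2], ess_after = f[3],
               log_sum_v = f[4])
  })
  mcols <- grep("^mean_", names(df), value = TRUE)
  means <- if (length(mcols)) {
    mn <- as.matrix(df[mcols])
    colnames(mn) <- sub("^mean_", "", mcols)
    mn
  } else NULL
  qcols <- setdiff(names(df), c("time", "ess", "loglik", "dt", mcols))
  quantiles <- NULL; qt_times <- NULL
  if (length(qcols)) {
    has_q <- rowSums(!is.na(df[qcols])) > 0
    qt_times <- df$time[has_q]
    coord <- unique(sub("_q[0-9.]+$", "", qcols))
    prob <- unique(sub("^.*_(q[0-9.]+)$", "\\1", qcols))
    quantiles <- array(NA_real_, c(sum(has_q), length(coord), length(prob)),
                       dimnames = list(NULL, coord, prob))
    for (k in seq_along(coord)) for (p in seq_along(prob))
      quantiles[, k, p] <- df[has_q, paste0(coord[k], "_", prob[p])]
  }
  filter_trace(df$time, df$ess, df$loglik,
               if (all(is.na(df$dt))) NULL else df$dt,
               qt_times, quantiles, events,
               n_particles = as.integer(np), means = means)
}
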