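#' Simulate trajectories of a birth-death-mutation process
#'
#' Exact stochastic simulation (Gillespie's direct method).  Waiting times
#' are exponential with the total propensity
#' `Lambda = sum_i (birth_i + death_i + mutation_i) Z_i`, and the event is
#' chosen proportionally to its propensity: a birth increments `Z_i`, a
#' death decrements it, and a mutation moves one cell from type `i` to type
#' `i+1`.  The run stops at extinction (`Lambda = 0`), at `t_max`, or when a
#' safety cap triggers.
#'
#' The state is recorded either at every event (`record = "events"`) or on
#' the supplied time grid (`record = "grid"`); grid recording stores the
#' state *just before* any event falling exactly on a grid time
#' (left-continuous convention).  Arrival times `T_k` (first time type `k`
#' is present) and extinction times `E_k` (last time it was present) are
#' always recorded exactly from the event sequence; `E_k` is reported as
#' censored when the run ends with type `k` still alive.
#'
#' Critical processes go extinct with probability one but have
#' infinite-mean extinction time, so unbounded runs need caps: exceeding
#' `max_events` or `max_cells` raises an error of class `"bdm_capped_run"`
#' carrying the partial trajectory in its `trajectory` field.
#'
#' @param object a [bdm_process()].
#' @param nsim number of trajectories; replicate `r` uses an independent
#'   substream derived from `(seed, r)`.
#' @param seed integer master seed; if `NULL` one is drawn from R's RNG.
#' @param t_max time horizon (may be `Inf` with `record = "events"`).
#' @param times recording grid for `record = "grid"`; defaults to 101
#'   equispaced points on `[0, t_max]`.
#' @param record `"grid"` or `"events"`.
#' @param max_events,max_cells safety caps per trajectory.
#' @param stop_on_arrival stop as soon as the first cell of the last type
#'   appears (useful for arrival-time sampling).
#' @param ... unused.
#' @return For `nsim = 1` a `bdm_trajectory`: a list with `times`, `counts`
#'   (matrix, one column per type), `arrivals`, `extinctions` (with
#'   `censored` flags), `seed`, `status` and the generating `spec`.  For
#'   `nsim > 1`, a list of such objects.
#' @examples
#' tr <- simulate(simple_bdm(2), seed = 1, t_max = 10)
#' tr$arrivals
#' @export
simulate.bdm_process <- function(object, nsim = 1, seed = NULL, t_max = Inf,
                                 times = NULL, record = c("grid", "events"),
                                 max_events = 1e8, max_cells = 1e7,
                                 stop_on_arrival = FALSE, ...) {
  record <- match.arg(record)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (!is.finite(t_max) && record == "grid" && is.null(times))
    record <- "events"
  if (record == "grid" && is.null(times))
    times <- seq(0, t_max, length.out = 101L)
  if (!is.null(times)) {
    stopifnot(all(diff(times) > 0), times[1] >= 0)
    if (any(times > t_max)) stop("grid times exceed t_max", call. = FALSE)
  }
  runs <- lapply(seq_len(nsim), function(r) {
    raw <- ssa_run_cpp(object$birth, object$death, object$mutation,
                       object$initial, t_max,
                       if (record == "grid") times else numeric(0),
                       record == "events", stop_on_arrival,
                       max_events, max_cells, as.integer(seed), r)
    traj <- build_trajectory(raw, object, record, times, seed, r)
    if (raw$status == 3L)
      stop(capped_run_condition(traj, max_events, max_cells))
    traj
  })
  if (nsim == 1) runs[[1]] else runs
}

build_trajectory <- function(raw, spec, record, times, seed, rep) {
  n <- spec$n
  if (record == "grid") {
    counts <- t(raw$grid_state)
    tt <- times
  } else {
    counts <- rbind(spec$initial, t(raw$event_state))
    tt <- c(0, raw$event_times)
  }
  colnames(counts) <- paste0("type", seq_len(n))
  structure(list(
    times = tt, counts = counts, record = record,
    arrivals = setNames(raw$arrival, paste0("type", seq_len(n))),
    extinctions = setNames(raw$extinct, paste0("type", seq_len(n))),
    censored = setNames(raw$alive_end == 1L, paste0("type", seq_len(n))),
    t_end = raw$t_end, n_events = raw$n_events,
    status = c("extinct", "t_max", "arrival", "capped")[raw$status + 1L],
    seed = seed, rep = rep, spec = spec), class = "bdm_trajectory")
}

capped_run_condition <- function(trajectory, max_events, max_cells) {
  errorCondition(
    sprintf("simulation cap exceeded (max_events = %g, max_cells = %g); partial trajectory attached",
            max_events, max_cells),
    class = c("bdm_capped_run", "bdm_error"),
    trajectory = trajectory)
}

#' Run a process until extinction
#'
#' Critical processes die out with probability one, so an uncapped run
#' terminates almost surely; the caps guard against the heavy tail of the
#' extinction time (its mean is infinite) and against non-critical rates.
#'
#' @inheritParams simulate.bdm_process
#' @param spec a [bdm_process()].
#' @return A `bdm_trajectory` with exact extinction times `E_k`.
#' @export
simulate_until_extinction <- function(spec, seed = NULL, max_events = 1e8,
                                      max_cells = 1e7) {
  simulate(spec, seed = seed, t_max = Inf, record = "events",
           max_events = max_events, max_cells = max_cells)
}

#' @export
print.bdm_trajectory <- function(x, ...) {
  cat(sprintf("bdm_trajectory: %d types, %s recording, %g events, status '%s'\n",
              x$spec$n, x$record, x$n_events, x$status))
  cat("arrivals:   ", paste(format(x$arrivals, digits = 4), collapse = " "), "\n")
  cat("extinctions:", paste(format(x$extinctions, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.bdm_trajectory <- function(x, ...) {
  n <- x$spec$n
  data.frame(rep = x$rep,
             time = rep(x$times, n),
             type = rep(seq_len(n), each = length(x$times)),
             count = as.vector(x$counts))
}

#' @export
plot.bdm_trajectory <- function(x, log = "", ...) {
  graphics::matplot(x$times, x$counts, type = "s", lty = 1, log = log,
                    xlab = "time", ylab = "cells", ...)
  graphics::legend("topright", colnames(x$counts), col = seq_len(x$spec$n),
                   lty = 1, bty = "n")
  invisible(x)
}

#' State of a trajectory at a time point
#'
#' Left-continuous lookup: the state at `t` is the state after the last
#' recorded change strictly before `t` (for `t = 0`, the initial state).
#'
#' @param traj a `bdm_trajectory`.
#' @param t time (scalar).
#' @return Numeric vector of per-type counts.
#' @export
trajectory_state <- function(traj, t) {
  if (traj$record == "grid") {
    i <- match(TRUE, abs(traj$times - t) < 1e-9)
    if (is.na(i)) stop("t is not on the recorded grid", call. = FALSE)
    return(traj$counts[i, ])
  }
  i <- findInterval(t, traj$times, left.open = TRUE)
  if (i < 1L) i <- 1L
  traj$counts[i, ]
}

#' Ensemble simulation with Monte-Carlo estimators
#'
#' Runs `reps` independent replicates (replicate `r` uses the substream
#' derived from `(seed, r)`) and aggregates them into estimators on the
#' grid: survival of the whole system and of the last type (with Wilson
#' confidence half-widths), per-type mean counts with standard errors
#' (extinct replicates contribute zeros), and exact per-replicate arrival
#' and extinction times.  Extinction times of types still alive at `t_max`
#' are censored.
#'
#' @inheritParams simulate.bdm_process
#' @param spec a [bdm_process()].
#' @param times recording grid (first point 0 recommended).
#' @param reps number of replicates.
#' @param conf_level confidence level of the Wilson intervals.
#' @param keep_counts also keep per-replicate counts of the total population
#'   and of the last type at every grid time (needed by [empirical_pmf()]
#'   on ensembles).
#' @return A `bdm_ensemble` object.
#' @examples
#' es <- bdm_ensemble(simple_bdm(1), times = c(0, 2, 4), reps = 2000, seed = 1)
#' es$survival_any$estimate  # compare 1/(1+t)
#' @export
bdm_ensemble <- function(spec, times, reps, seed = NULL, t_max = max(times),
                         conf_level = 0.95, keep_counts = FALSE,
                         stop_on_arrival = FALSE,
                         max_events = 1e8, max_cells = 1e7) {
  stopifnot(inherits(spec, "bdm_process"), reps >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  stopifnot(all(diff(times) > 0), times[1] >= 0)
  raw <- ssa_ensemble_cpp(spec$birth, spec$death, spec$mutation, spec$initial,
                          times, t_max, as.integer(reps), as.integer(seed),
                          max_events, max_cells, stop_on_arrival, keep_counts)
  if (any(raw$status == 3L))
    stop(sprintf("%d of %d replicates exceeded the simulation caps",
                 sum(raw$status == 3L), reps), call. = FALSE)
  n <- spec$n
  mean_counts <- t(raw$sum_counts) / reps
  var_counts <- t(raw$sumsq_counts) / reps - mean_counts^2
  var_counts[var_counts < 0] <- 0
  se_counts <- sqrt(var_counts / reps)
  colnames(mean_counts) <- colnames(se_counts) <- paste0("type", seq_len(n))
  tn <- paste0("type", seq_len(n))
  colnames(raw$arrivals) <- colnames(raw$extinctions) <- colnames(raw$censored) <- tn
  structure(list(
    spec = spec, times = times, reps = reps, seed = seed,
    survival_any = wilson_interval(raw$alive_any, reps, conf_level),
    survival_last = wilson_interval(raw$alive_last, reps, conf_level),
    mean_counts = mean_counts, se_counts = se_counts,
    arrivals = raw$arrivals, extinctions = raw$extinctions,
    censored = raw$censored, n_events = raw$n_events,
    counts_total = if (keep_counts) raw$counts_total,
    counts_last = if (keep_counts) raw$counts_last,
    conf_level = conf_level), class = "bdm_ensemble")
}

wilson_interval <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, lower = pmax(0, centre - hw), upper = pmin(1, centre + hw),
       halfwidth = hw)
}

#' @export
print.bdm_ensemble <- function(x, ...) {
  cat(sprintf("bdm_ensemble: %d replicates of a %d-type process, %d grid points, seed %d\n",
              x$reps, x$spec$n, length(x$times), x$seed))
  i <- length(x$times)
  cat(sprintf("survival at t = %g: whole system %.4f, last type %.4f\n",
              x$times[i], x$survival_any$estimate[i], x$survival_last$estimate[i]))
  invisible(x)
}

#' Empirical probability mass function from simulations
#'
#' Histogram of the number of cells across replicates at one recorded time,
#' normalized to a probability mass function, optionally conditioned on the
#' count being positive.
#'
#' @param x a `bdm_ensemble` built with `keep_counts = TRUE`, or a list of
#'   `bdm_trajectory` objects.
#' @param t a time on the recorded grid.
#' @param which `"total"` for the whole population, `"last"` for the last
#'   type; for a trajectory list, a type index is also accepted.
#' @param conditional condition on a positive count.
#' @return A `bdm_pmf` object with fields `s`, `prob`, `t` and provenance
#'   metadata.
#' @export
empirical_pmf <- function(x, t, which = "total", conditional = FALSE) {
  if (inherits(x, "bdm_ensemble")) {
    if (is.null(x$counts_total))
      stop("build the ensemble with keep_counts = TRUE", call. = FALSE)
    g <- match(TRUE, abs(x$times - t) < 1e-9)
    if (is.na(g)) stop("t is not on the recorded grid", call. = FALSE)
    counts <- switch(as.character(which),
                     total = x$counts_total[, g],
                     last = x$counts_last[, g],
                     stop("`which` must be 'total' or 'last' for ensembles",
                          call. = FALSE))
  } else {
    counts <- vapply(x, function(tr) {
      st <- trajectory_state(tr, t)
      if (identical(which, "total")) sum(st) else st[[as.integer(which)]]
    }, numeric(1))
  }
  if (conditional) counts <- counts[counts > 0]
  if (length(counts) == 0) stop("no replicates satisfy the condition", call. = FALSE)
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  structure(list(s = 0:max(counts), prob = tab / length(counts), t = t,
                 provenance = "empirical", n = length(counts),
                 deficit = 0, radius = NA_real_, max_imag = NA_real_),
            class = "bdm_pmf")
}
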