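#' Survival, presence and arrival ODE systems of the n-type process
#'
#' Three backwards-coupled families of ordinary differential equations
#' govern the probabilities of the simple n-type critical process; each is
#' solved here with an adaptive implicit-capable integrator (lsoda) at
#' tight tolerances.
#'
#' * **survival** `S_i(t)`: probability that any cell of any type is alive
#'   at `t` starting from one type-`i` cell; `dS_i/dt = S_(i+1) - S_i^2`
#'   for `i < n`, `dS_n/dt = -S_n^2`, all `S_i(0) = 1`.  The last component
#'   is always the single-type closed form `1/(1+t)`.
#' * **presence** `Q_i(t)`: probability that at least one type-`n` cell is
#'   alive at `t`; the same equations with `Q_i(0) = 0` for `i < n` and
#'   `Q_n(0) = 1`.
#' * **arrival** `g_i(t)`: probability that the first type-`n` cell has
#'   appeared by `t`, in the critical family with division rate 1 and
#'   constant mutation rate `nu` (death rate `1 - nu`);
#'   `dg_i/dt = -g_i^2 + nu g_(i+1)` with `g_i(0) = 0` and `g_n == 1`.
#'   The system is integrated in `g` (rather than `h = 1 - g`) because the
#'   quadratic form is better conditioned near the defective limit.
#'
#' Values are clipped to `[0, 1]` only in the returned matrix, never in the
#' solver state, so convergence diagnostics stay honest.
#'
#' @param n number of types (`n >= 1` for survival, `n >= 2` otherwise).
#' @param times strictly increasing time grid; 0 is prepended when absent.
#' @param nu mutation rate in `(0, 1]` (arrival system only).
#' @param rtol,atol solver tolerances.
#' @return A `bdm_ode` object: list with `system`, `n`, `nu`, `times`, and
#'   `values`, a matrix with one row per grid point and one column per
#'   component (column `i` starts the process from a single type-`i` cell;
#'   for the arrival system column `n` is identically 1).
#' @examples
#' sol <- solve_survival(3, times = c(0, 1, 10, 100))
#' sol$values[, 1]  # whole-system survival from one type-1 cell
#' @export
solve_survival <- function(n, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(n >= 1)
  solve_bdm_system("survival", n, times, y0 = rep(1, n),
                   rhs = function(t, y, p) list(c(y[-1], 0) - y^2),
                   nu = NA_real_, rtol = rtol, atol = atol)
}

#' @rdname solve_survival
#' @export
solve_presence <- function(n, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(n >= 2)
  solve_bdm_system("presence", n, times, y0 = c(rep(0, n - 1), 1),
                   rhs = function(t, y, p) list(c(y[-1], 0) - y^2),
                   nu = NA_real_, rtol = rtol, atol = atol)
}

#' @rdname solve_survival
#' @export
solve_arrival <- function(n, nu = 1, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(n >= 2)
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]", call. = FALSE)
  # g_n == 1 is an algebraic constraint, so only g_1..g_{n-1} are state
  sol <- solve_bdm_system("arrival", n, times, y0 = rep(0, n - 1),
                          rhs = function(t, y, p) list(-y^2 + nu * c(y[-1], 1)),
                          nu = nu, rtol = rtol, atol = atol,
                          n_state = n - 1L)
  sol$values <- cbind(sol$values, 1)
  colnames(sol$values) <- paste0("from_type", seq_len(n))
  sol
}

solve_bdm_system <- function(system, n, times, y0, rhs, nu, rtol, atol,
                             n_state = n) {
  stopifnot(all(diff(times) > 0), times[1] >= 0)
  prepend <- times[1] > 0
  tt <- if (prepend) c(0, times) else times
  sol <- deSolve::ode(y = y0, times = tt, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 100000)
  if (attr(sol, "istate")[1] != 2)
    stop(sprintf("ODE solver failed for the %s system (n = %d): istate = %d",
                 system, n, attr(sol, "istate")[1]), call. = FALSE)
  vals <- unname(sol[, -1, drop = FALSE])
  if (prepend) vals <- vals[-1, , drop = FALSE]
  vals <- pmin(pmax(vals, 0), 1)
  dim(vals) <- c(length(times), n_state)
  colnames(vals) <- paste0("from_type", seq_len(n_state))
  structure(list(system = system, n = n, nu = nu, times = times,
                 values = vals, rtol = rtol, atol = atol, solver = "lsoda"),
            class = "bdm_ode")
}

#' @export
print.bdm_ode <- function(x, ...) {
  cat(sprintf("bdm_ode: %s system, n = %d%s, %d grid points on [%g, %g]\n",
              x$system, x$n,
              if (!is.na(x$nu)) sprintf(", nu = %g", x$nu) else "",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.bdm_ode <- function(x, log = "x", ...) {
  tt <- x$times
  keep <- if (grepl("x", log)) tt > 0 else rep(TRUE, length(tt))
  graphics::matplot(tt[keep], x$values[keep, , drop = FALSE], type = "l",
                    lty = 1, log = log, xlab = "time",
                    ylab = paste(x$system, "probability"), ...)
  invisible(x)
}

#' Limiting arrival probability and the maximal type
#'
#' In the critical family with constant mutation rate `nu`, the first
#' type-`n` cell ever appears with probability `nu^(1 - chi_n)`,
#' `chi_n = 2^(1-n)`: setting the arrival system's time derivatives to zero
#' gives the fixed point.  With `M` the maximal type that ever appears,
#' `P(M >= n) = nu^(1 - chi_n)`; the conditional odds
#' `P(M >= n+1 | M >= n) = nu^(2^-n)` tend to 1, so the mean of `M` is
#' infinite even for small `nu`.
#'
#' @param n type index (`n >= 1`).
#' @param nu mutation rate in `(0, 1]`.
#' @param check_ode also solve the arrival ODE system out to a horizon
#'   proportional to the relaxation time `nu^-(1 - chi_n)` and return the
#'   numerical limit alongside the closed form.
#' @return `arrival_limit()`: the probability `nu^(1 - chi_n)` (or a named
#'   vector `c(closed, ode)` when `check_ode` is set).
#' @examples
#' arrival_limit(3, 0.5)  # 0.5^(3/4)
#' @export
arrival_limit <- function(n, nu, check_ode = FALSE) {
  stopifnot(n >= 1)
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]", call. = FALSE)
  closed <- nu^(1 - chi_exponent(n))
  if (!check_ode || n < 2) return(closed)
  horizon <- 20 / closed
  sol <- solve_arrival(n, nu, times = c(0, horizon))
  c(closed = closed, ode = unname(sol$values[2, 1]))
}

#' @rdname arrival_limit
#' @param n_max largest type index to report.
#' @return `maximal_type_law()`: the vector `P(M >= n)` for `n = 1..n_max`.
#' @export
maximal_type_law <- function(nu, n_max) {
  vapply(seq_len(n_max), arrival_limit, numeric(1), nu = nu)
}

#' Mean arrival time of the first type-n cell
#'
#' `E T_n = integral of 1 - g_(1,n)(t)`, computed by augmenting the arrival
#' ODE system with the integral as an extra state (so the quadrature
#' inherits the solver tolerances).  For the pure birth-mutation process
#' the mean arrival of the first type-2 cell is `log 2`.  The integrand
#' decays exponentially, so a modest horizon suffices; for `nu < 1` the
#' arrival law is defective and the conditional mean is not computed here.
#'
#' @param n type index, `n >= 2`.
#' @param nu mutation rate (must be 1, the proper-arrival case).
#' @param upper integration horizon; the neglected tail is
#'   `O(exp(-2 upper))` for `n = 2`.
#' @param rtol,atol solver tolerances.
#' @return The mean arrival time.
#' @examples
#' expected_arrival_time(2)  # log(2)
#' @export
expected_arrival_time <- function(n, nu = 1, upper = 30, rtol = 1e-10,
                                  atol = 1e-12) {
  stopifnot(n >= 2)
  if (nu != 1)
    stop("the mean is only finite-and-proper for nu = 1", call. = FALSE)
  rhs <- function(t, y, p) {
    g <- y[seq_len(n - 1)]
    list(c(-g^2 + nu * c(g[-1], 1)[seq_len(n - 1)], 1 - g[1]))
  }
  sol <- deSolve::ode(c(rep(0, n - 1), 0), c(0, upper), rhs, NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 100000)
  if (attr(sol, "istate")[1] != 2)
    stop("ODE solver failed in expected_arrival_time", call. = FALSE)
  unname(sol[2, n + 1])
}

#' High-accuracy survival of the penultimate type
#'
#' The survival probability starting from one penultimate-type cell solves
#' `dS/dt = 1/(1+t) - S^2`, `S(0) = 1` (the same equation for every `n`).
#' For extracting the coefficients of its large-time expansion
#' `(1+t)^(-1/2) + (1/4)(1+t)^-1 + (3/32)(1+t)^(-3/2) + ...` the plain
#' formulation loses precision, so this routine integrates the rescaled
#' variable `w = sqrt(1+t) S` on log-time, `w' = w/2 + e^(s/2) (1 - w^2)`
#' with `s = log(1+t)`, which keeps `w = O(1)` on arbitrarily long
#' horizons and resolves the residual terms to ~1e-12.
#'
#' @param t times, `t >= 0` (vectorized, increasing).
#' @param rtol,atol solver tolerances.
#' @return `S(t)` to near machine accuracy.
#' @examples
#' (survival_penultimate_ode(1e6) * sqrt(1 + 1e6) - 1) * sqrt(1 + 1e6)  # ~ 1/4
#' @export
survival_penultimate_ode <- function(t, rtol = 1e-13, atol = 1e-13) {
  stopifnot(all(t >= 0), !is.unsorted(t))
  s <- log(1 + t)
  tt <- if (s[1] > 0) c(0, s) else s
  sol <- deSolve::ode(c(w = 1), tt,
                      function(s, y, p) list(y[1] / 2 + exp(s / 2) * (1 - y[1]^2)),
                      NULL, method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 100000)
  if (attr(sol, "istate")[1] != 2)
    stop("ODE solver failed in survival_penultimate_ode", call. = FALSE)
  w <- sol[, "w"]
  if (s[1] > 0) w <- w[-1]
  w / sqrt(1 + t)
}
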