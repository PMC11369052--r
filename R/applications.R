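#' Shannon diversity of a simulated population
#'
#' `H'(t) = -sum_i p_i(t) log p_i(t)` with `p_i` the proportion of type-`i`
#' cells, using the convention `0 log 0 = 0`; `H'` is recorded as `NA`
#' while the population is extinct.  In the critical mutation-accumulation
#' process the index typically rises while the first mutations accumulate,
#' peaks around the arrival of the last type, and then collapses as the
#' last type takes over.
#'
#' @param x a `bdm_trajectory`, or a list of them (then the mean of `H'`
#'   over the replicates surviving at each time is returned).
#' @param times evaluation times; defaults to the recorded grid of (the
#'   first) trajectory.
#' @param base logarithm base; natural log by default, so the maximum over
#'   `n` types is `log(n)`.
#' @return A data frame with columns `time` and `shannon` (and
#'   `n_surviving` for the ensemble-mean version).
#' @export
shannon_index <- function(x, times = NULL, base = exp(1)) {
  if (inherits(x, "bdm_trajectory")) {
    if (is.null(times)) times <- x$times
    h <- vapply(times, function(t) shannon_at(trajectory_state(x, t), base),
                numeric(1))
    return(data.frame(time = times, shannon = h))
  }
  stopifnot(is.list(x), length(x) > 0, inherits(x[[1]], "bdm_trajectory"))
  if (is.null(times)) times <- x[[1]]$times
  H <- vapply(x, function(tr)
    vapply(times, function(t) shannon_at(trajectory_state(tr, t), base),
           numeric(1)), numeric(length(times)))
  H <- matrix(H, nrow = length(times))
  data.frame(time = times,
             shannon = rowMeans(H, na.rm = TRUE),
             n_surviving = rowSums(!is.na(H)))
}

shannon_at <- function(counts, base = exp(1)) {
  tot <- sum(counts)
  if (tot <= 0) return(NA_real_)
  p <- counts[counts > 0] / tot
  -sum(p * log(p)) / log(base)
}

#' Expected number of co-existing types
#'
#' `K_n(t)`, the expected number of types present at time `t` in the simple
#' n-type process, equals the sum over `i = 1..n` of the probability that
#' type-`i` cells are present.  By decomposability the presence probability
#' of type `i` equals the type-presence probability `Q` of the `i`-type
#' process (with `Q = S = 1/(1+t)` for `i = 1`), so `K_n` is assembled
#' from the ODE presence solutions.  At large times
#' `K_n(t) ~ t^(-chi_n)`: diversity rises, peaks within tens of
#' generations, and then decays — unlike an unboundedly mutating
#' population, whose expected number of types keeps growing.
#'
#' @param n number of types.
#' @param times evaluation grid.
#' @param ... passed to [solve_presence()].
#' @return A data frame with columns `time`, `k_types` and the leading
#'   large-time asymptote `leading` (`t^(-chi_n)`).
#' @examples
#' expected_types(3, times = c(0, 1, 10, 100))
#' @export
expected_types <- function(n, times, ...) {
  stopifnot(n >= 1)
  K <- single_type_survival(times)
  if (n >= 2)
    for (i in 2:n)
      K <- K + solve_presence(i, times, ...)$values[, 1]
  data.frame(time = times, k_types = K,
             leading = ifelse(times > 0, times^(-chi_exponent(n)), NA_real_))
}

#' Colony survival after a number of generations
#'
#' With division rate one, time is measured in generations, and the
#' probability that a colony started from a single cell still has living
#' cells after `t` generations is the whole-system survival probability:
#' exact for `n <= 2` (rational, respectively Bessel, closed forms), from
#' the survival ODE system for `n >= 3`.  The labeled fast path
#' `method = "expansion"` evaluates the two-term large-time expansion
#' instead.
#'
#' @param n maximal number of mutations a cell can accumulate.
#' @param t number of generations (vectorized).
#' @param method `"auto"` (exact/ODE) or `"expansion"`.
#' @return Survival probability after `t` generations.
#' @examples
#' survival_after_generations(1, 10)  # 1/11
#' @export
survival_after_generations <- function(n, t, method = c("auto", "expansion")) {
  method <- match.arg(method)
  stopifnot(n >= 1, all(t >= 0))
  if (method == "expansion")
    return(evaluate_expansion(survival_expansion(n, order = min(2, n)), t))
  if (n == 1) return(single_type_survival(t))
  if (n == 2) return(two_type_survival(t))
  tu <- sort(unique(c(0, t)))
  sol <- solve_survival(n, times = tu)
  sol$values[match(t, tu), 1]
}

#' @rdname survival_after_generations
#' @param p target survival probability in `(0, 1)`.
#' @return `generations_to_survival()`: the smallest `t` with survival
#'   probability `p`, found by bracketing on the exact/ODE survival (the
#'   expansion-based estimate is attached as attribute `"expansion"` for
#'   comparison).
#' @examples
#' generations_to_survival(1, 0.1)  # 9 generations
#' @export
generations_to_survival <- function(n, p) {
  stopifnot(n >= 1)
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  chi <- chi_exponent(n)
  upper <- 10 * max(1, p^(-1 / chi))
  f <- if (n == 1) single_type_survival
  else if (n == 2) two_type_survival
  else {
    grid <- time_grid(upper, length.out = 600L, spacing = "log")
    sol <- solve_survival(n, grid)
    # monotone interpolation on log(1+t); survival is strictly decreasing
    function(t) exp(approx(log1p(grid), log(pmax(sol$values[, 1], 1e-300)),
                           xout = log1p(t))$y)
  }
  root <- uniroot(function(t) f(t) - p, c(0, upper), tol = 1e-8)$root
  expansion_est <- if (n == 1) 1 / p - 1 else
    uniroot(function(t) evaluate_expansion(survival_expansion(n, 2), t) - p,
            c(0, upper * 10), tol = 1e-8)$root
  structure(root, expansion = expansion_est)
}

#' Expected colony size
#'
#' `sum_(i=1..n) t^(i-1)/(i-1)!`: the mean total population of the
#' n-type process after `t` generations.  It grows like `e^t` while
#' `t << n` (the Yule phase of unbounded mutation accumulation) and
#' plateaus to algebraic growth `t^(n-1)/(n-1)!` afterwards; the
#' corresponding `e^t` reference is attached as attribute
#' `"yule_reference"`.
#'
#' @param n maximal number of mutations.
#' @param t generations (vectorized).
#' @return Mean total cell number with the exponential reference attached.
#' @examples
#' expected_colony_size(2, 20)  # 21 cells on average
#' @export
expected_colony_size <- function(n, t) {
  stopifnot(n >= 1, all(t >= 0))
  out <- numeric(length(t))
  for (i in seq_len(n)) out <- out + mean_type_count(i, t)
  structure(out, yule_reference = exp(t))
}
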