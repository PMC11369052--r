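#' The survival exponent family chi_n = 2^(1-n)
#'
#' A single family of exponents governs the large-time behaviour of the
#' simple n-type critical process: the whole-system survival probability
#' decays as `(1+t)^(-chi_n)`, the generating function behaves as
#' `(t + (1-x_n)^-1)^(-chi_n)`, and the cell-number mass functions develop
#' an algebraic tail `size^(-1-chi_n)`.
#'
#' @param n type count, `n >= 1` (vectorized).
#' @return `2^(1-n)`.
#' @examples
#' chi_exponent(1:5)  # 1, 1/2, 1/4, 1/8, 1/16
#' @export
chi_exponent <- function(n) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  2^(1 - n)
}

#' Matched-asymptotic expansion of the survival probability
#'
#' Large-time expansions in powers of `(1+t)`, obtained by substituting
#' power-law ansatz terms into the survival ODEs and matching
#' coefficients.  For general `n >= 2` the two-term expansion of the
#' whole-system survival is
#' `S_(1,n) ~ (1+t)^(-chi_n) + (chi_n/2) (1+t)^(-1/2-chi_n)`; for `n = 1`
#' the single leading term `(1+t)^-1` is exact.  For the penultimate-type
#' start (equivalently `n = 2`) a third term is available:
#' `(1+t)^(-1/2) + (1/4)(1+t)^-1 + (3/32)(1+t)^(-3/2)`.
#'
#' @param n number of types.
#' @param order number of terms (1 to 3; 3 only for `n = 2`).
#' @return A `bdm_expansion`: list of `terms` (matrix with columns
#'   `coefficient` and `exponent`, meaning
#'   `coefficient * (1+t)^-exponent`), evaluable with
#'   [evaluate_expansion()].
#' @examples
#' evaluate_expansion(survival_expansion(2, 3), 100)
#' @export
survival_expansion <- function(n, order = 2) {
  stopifnot(n >= 1, order >= 1)
  chi <- chi_exponent(n)
  terms <- rbind(c(1, chi))
  if (order >= 2) {
    if (n == 1)
      stop("the single-type survival 1/(1+t) is exact: no higher-order terms",
           call. = FALSE)
    terms <- rbind(terms, c(chi / 2, 1 / 2 + chi))
  }
  if (order >= 3) {
    if (n != 2 || order > 3)
      stop("third-order terms are only available for the penultimate-type case (n = 2)",
           call. = FALSE)
    terms <- rbind(terms, c(3 / 32, 3 / 2))
  }
  colnames(terms) <- c("coefficient", "exponent")
  structure(list(target = sprintf("S_{1,%d}", n), n = n, order = order,
                 terms = terms), class = "bdm_expansion")
}

#' @rdname survival_expansion
#' @param expansion a `bdm_expansion`.
#' @param t times, `t >= 0` (vectorized).
#' @export
evaluate_expansion <- function(expansion, t) {
  stopifnot(inherits(expansion, "bdm_expansion"))
  tm <- expansion$terms
  out <- numeric(length(t))
  for (k in seq_len(nrow(tm)))
    out <- out + tm[k, "coefficient"] * (1 + t)^(-tm[k, "exponent"])
  out
}

#' @export
print.bdm_expansion <- function(x, ...) {
  cat(sprintf("large-time expansion of %s, %d term(s):\n", x$target, x$order))
  cat(paste(sprintf("%.6g * (1+t)^-%.6g", x$terms[, 1], x$terms[, 2]),
            collapse = " + "), "\n")
  invisible(x)
}

# Kummer's confluent hypergeometric M(1 + chi, 2, -y) for y >= 0.
# Uses the Kummer transformation M(1+chi, 2, -y) = e^-y M(1-chi, 2, y),
# whose series has positive terms (no cancellation), below the switch
# point; beyond it, the large-argument asymptotic branch
# M(1+chi,2,-y) ~ y^(-1-chi)/Gamma(1-chi) * sum_k (1+chi)_k (chi)_k / (k! y^k).
kummer_m_neg <- function(chi, y, switch_at = 30, terms = 20L) {
  if (chi == 1) return(exp(-y))  # M(2; 2; -y) exactly
  out <- numeric(length(y))
  lo <- y < switch_at
  if (any(lo)) {
    yl <- y[lo]
    term <- rep(1, length(yl))
    acc <- term
    k <- 0
    a <- 1 - chi
    repeat {
      term <- term * (a + k) / ((2 + k) * (k + 1)) * yl
      acc <- acc + term
      k <- k + 1
      if (max(term) < 1e-17 * max(acc) || k > 500) break
    }
    out[lo] <- exp(-yl) * acc
  }
  if (any(!lo)) {
    yh <- y[!lo]
    term <- rep(1, length(yh))
    acc <- term
    for (k in seq_len(terms) - 1) {
      term <- term * (1 + chi + k) * (chi + k) / ((k + 1) * yh)
      acc <- acc + term
    }
    out[!lo] <- yh^(-1 - chi) / gamma(1 - chi) * acc
  }
  out
}

#' Scaling density of the cell number conditioned on survival
#'
#' Conditioned on type-`n` survival, `Z_n(t)/t` converges in distribution
#' to a limit `Y_n` with density
#' `f(y) = chi_n F(1 + chi_n; 2; -y)` (confluent hypergeometric) and
#' Laplace transform `E e^(-p Y_n) = 1 - (p/(p+1))^chi_n`.  For `n = 1`
#' this is the exponential limit `e^-y` of the geometric law.  Large
#' arguments use the asymptotic branch of the hypergeometric function
#' (switching at `y = 30`) to avoid cancellation.
#'
#' @param n number of types.
#' @param y non-negative argument (vectorized).
#' @return `scaling_density()`: the density `f_(Y_n)(y)`.
#' @examples
#' scaling_density(1, 2)  # exp(-2)
#' @export
scaling_density <- function(n, y) {
  if (any(y < 0)) stop("y must be non-negative", call. = FALSE)
  chi <- chi_exponent(n)
  chi * kummer_m_neg(chi, y)
}

#' @rdname scaling_density
#' @param p non-negative Laplace variable (vectorized).
#' @return `scaling_laplace()`: `1 - (p/(p+1))^chi_n`.
#' @export
scaling_laplace <- function(n, p) {
  if (any(p < 0)) stop("p must be non-negative", call. = FALSE)
  1 - (p / (p + 1))^chi_exponent(n)
}

#' Scaling form and stationary tail of the cell-number mass function
#'
#' The large-time approximation to the probability of finding `s` type-`n`
#' cells (or, asymptotically equivalently, `s` cells in total) is
#' `P_s(t) ~ chi_n t^(-1-chi_n) F(1 + chi_n; 2; -s/t)`.  In the window
#' `t << s << s_* = t^((n-1)/(1-chi_n))` the hypergeometric asymptote
#' makes the tail algebraic *and stationary*:
#' `P_s ~ chi_n / Gamma(1 - chi_n) * s^(-1-chi_n)`, independent of `t`.
#' The upper cutoff `s_*` is fixed by consistency with the finite mean
#' `E Z_n = t^(n-1)/(n-1)!` and is an order of magnitude only.
#'
#' @param n number of types (`n >= 2` for the tail: the single-type law
#'   has an exponential, not algebraic, tail).
#' @param s cell count (vectorized).
#' @param t time, `t > 0`.
#' @return `pmf_scaling()`: the scaling-form approximation to `P_s(t)`.
#' @examples
#' pmf_scaling(2, s = 100, t = 50)
#' @export
pmf_scaling <- function(n, s, t) {
  stopifnot(t > 0)
  if (any(s < 0)) stop("s must be non-negative", call. = FALSE)
  chi <- chi_exponent(n)
  chi * t^(-1 - chi) * kummer_m_neg(chi, s / t)
}

#' @rdname pmf_scaling
#' @export
pmf_tail <- function(n, s) {
  if (any(n < 2)) stop("n must be >= 2: the single-type tail is exponential",
                       call. = FALSE)
  chi <- chi_exponent(n)
  chi / gamma(1 - chi) * s^(-1 - chi)
}

#' @rdname pmf_scaling
#' @param lo_factor,hi_factor margins operationalizing the "much less
#'   than" bounds of the validity window (default factor 5 on each side).
#' @return `tail_window()`: the window `c(s_lo, s_hi)` on which the
#'   stationary tail applies at time `t`.
#' @export
tail_window <- function(n, t, lo_factor = 5, hi_factor = 5) {
  stopifnot(n >= 2, t > 0)
  chi <- chi_exponent(n)
  c(s_lo = lo_factor * t, s_hi = t^((n - 1) / (1 - chi)) / hi_factor)
}

#' Scaling limit of the arrival-time law
#'
#' For small mutation rate `nu`, the probability that the first type-`n`
#' cell has arrived by time `t` collapses onto
#' `g(t) ~ nu^(1-chi_n) tanh(nu^(1-chi_n) t)`: the limiting probability
#' `nu^(1-chi_n)` also sets the time scale.  For `n = 2` the formula is
#' exact for every `nu`.
#'
#' @param n type index, `n >= 2`.
#' @param nu mutation rate in `(0, 1]`.
#' @param t time, `t >= 0` (vectorized).
#' @return Approximate `P(T_n <= t)`.
#' @export
arrival_scaling <- function(n, nu, t) {
  stopifnot(n >= 2)
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]", call. = FALSE)
  a <- nu^(1 - chi_exponent(n))
  a * tanh(a * t)
}
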