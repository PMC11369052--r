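#' Closed-form results for the single-type critical process
#'
#' For a single critical type (division and lethal mutation both at rate
#' one, one initial cell) everything is explicit: the survival probability
#' is `1/(1+t)`, the number of cells conditioned on survival is geometric
#' with success probability `1/(1+t)`, and the mean count stays exactly 1.
#'
#' @param t time, `t >= 0` (vectorized).
#' @return `single_type_survival()`: the probability that any cell is alive
#'   at `t`.
#' @examples
#' single_type_survival(10)  # 1/11: under 10% after 10 generations
#' @export
single_type_survival <- function(t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  1 / (1 + t)
}

#' @rdname single_type_survival
#' @param a cell count, `a >= 0` (vectorized).
#' @return `single_type_pmf()`: `P(Z_1(t) = a)`, i.e. `t/(1+t)` for
#'   `a = 0` and `(1+t)^-2 (t/(1+t))^(a-1)` for `a >= 1`.
#' @export
single_type_pmf <- function(a, t) {
  if (any(a < 0) || any(a != round(a))) stop("a must be a non-negative integer", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  ifelse(a == 0, t / (1 + t), (1 + t)^-2 * (t / (1 + t))^(a - 1))
}

#' @rdname single_type_survival
#' @param x generating-function argument, `|x| <= 1` (possibly complex).
#' @return `single_type_gf()`: the probability generating function
#'   `E(x^Z_1(t))`, equal to `(t(1-x) + x) / (t(1-x) + 1)`.
#' @export
single_type_gf <- function(x, t) {
  (t * (1 - x) + x) / (t * (1 - x) + 1)
}

#' The Yule total population of the infinite-type process
#'
#' With unboundedly many types, every sub-population is critical but the
#' total population, ignoring types, is a pure-birth (Yule) process at rate
#' one: `P(Z(t) = s) = e^-t (1 - e^-t)^(s-1)` and `E Z(t) = e^t`.
#'
#' @param s total count, `s >= 1` (vectorized).
#' @param t time, `t >= 0`.
#' @export
yule_pmf <- function(s, t) {
  if (any(s < 1)) stop("s must be >= 1", call. = FALSE)
  exp(-t) * (1 - exp(-t))^(s - 1)
}

#' @rdname yule_pmf
#' @export
yule_mean <- function(t) exp(t)

# survival amplitude (I0(2) - I1(2)) / (K0(2) + K1(2)), evaluated once
two_type_c_constant <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- (besselI(2, 0) - besselI(2, 1)) / (besselK(2, 0) + besselK(2, 1))
    val
  }
})

#' Exact two-type survival probability
#'
#' For the simple two-type critical process started from one type-1 cell,
#' the whole-system survival probability solves a Riccati equation whose
#' solution is a ratio of modified Bessel functions,
#' `S(t) = (1/tau) * (I0(2 tau) - c K0(2 tau)) / (I1(2 tau) + c K1(2 tau))`
#' with `tau = sqrt(1+t)` and the amplitude
#' `c = (I0(2) - I1(2)) / (K0(2) + K1(2))` fixed by `S(0) = 1`.  The
#' implementation uses exponentially scaled Bessel functions with the
#' scaling cancelled algebraically, so it is stable for `t` up to `1e8` and
#' beyond (naive evaluation overflows near `t ~ 700`).
#'
#' @param t time, `t >= 0` (vectorized).
#' @return Survival probability; decays like `(1+t)^(-1/2)` for large `t`.
#' @examples
#' two_type_survival(c(0, 10, 1e6))
#' @export
two_type_survival <- function(t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  tau <- sqrt(1 + t)
  i0 <- besselI(2 * tau, 0, expon.scaled = TRUE)
  i1 <- besselI(2 * tau, 1, expon.scaled = TRUE)
  k0 <- besselK(2 * tau, 0, expon.scaled = TRUE)
  k1 <- besselK(2 * tau, 1, expon.scaled = TRUE)
  # With I_nu(z) = i e^{z} and K_nu(z) = k e^{-z}, the common e^{2 tau}
  # cancels in the ratio and the amplitude picks up e^{-4 tau}; writing
  # c = ce * e^{4} from scaled values at z = 2 keeps every factor bounded.
  ce <- (besselI(2, 0, expon.scaled = TRUE) - besselI(2, 1, expon.scaled = TRUE)) /
    (besselK(2, 0, expon.scaled = TRUE) + besselK(2, 1, expon.scaled = TRUE))
  g0 <- ce * exp(4 - 4 * tau)
  (i0 - g0 * k0) / (i1 + g0 * k1) / tau
}

#' Exact two-type probability generating function
#'
#' Joint generating function `E(x1^Z1 x2^Z2)` of the simple two-type
#' critical process started from one type-1 cell, in closed Bessel form
#' with `tau = sqrt(t + (1-x2)^-1)` (principal square root) and the
#' amplitude fixed by the initial condition (value `x1` at `t = 0`).
#' Evaluated with exponentially scaled Bessel functions so that contour
#' evaluations with `|x2|` close to 1 do not overflow.  Setting
#' `x1 = x2 = 0` recovers `1 -` [two_type_survival()].
#'
#' @param x1,x2 generating-function arguments with `|x| <= 1`; `x2 = 1` is
#'   a singular point and raises an error (use the closed forms for the
#'   type-1 marginal instead).  Vectors of equal length are accepted.
#' @param t time, scalar `t >= 0`.
#' @return Complex vector of generating-function values.
#' @examples
#' Re(two_type_gf(0, 0, 5)) + two_type_survival(5)  # = 1
#' @export
two_type_gf <- function(x1, x2, t) {
  stopifnot(length(t) == 1L, t >= 0)
  if (any(abs(1 - x2) < 1e-14))
    stop("x2 = 1 is a singular argument of the two-type generating function",
         call. = FALSE)
  x1 <- as.complex(x1); x2 <- as.complex(x2)
  m <- max(length(x1), length(x2))
  x1 <- rep_len(x1, m); x2 <- rep_len(x2, m)
  tau0 <- sqrt(1 / (1 - x2))
  tau <- sqrt(t + 1 / (1 - x2))
  zmax <- max(2 * Mod(tau), 2 * Mod(tau0))
  nodes <- max(800L, 4L * ceiling(zmax))
  # amplitude c with the e^{4 tau0} growth folded against e^{-4 tau}:
  # Re(tau) >= Re(tau0) for t >= 0, so the factor never overflows
  gam <- exp(4 * (tau0 - tau)) *
    (besselIe_c(2 * tau0, 0, nodes) - (1 - x1) * tau0 * besselIe_c(2 * tau0, 1, nodes)) /
    (besselKe_c(2 * tau0, 0) + (1 - x1) * tau0 * besselKe_c(2 * tau0, 1))
  (1 - (besselIe_c(2 * tau, 0, nodes) - gam * besselKe_c(2 * tau, 0)) /
     (besselIe_c(2 * tau, 1, nodes) + gam * besselKe_c(2 * tau, 1)) / tau)
}

#' Mean number of type-i cells
#'
#' In the simple n-type critical process started from one type-1 cell the
#' means satisfy `d E(Z_i)/dt = E(Z_(i-1))`, giving
#' `E Z_i(t) = t^(i-1) / (i-1)!` — independent of `n` for `i <= n`.
#' Summed over all `i` this recovers the Yule mean `e^t`.
#'
#' @param i type index, `i >= 1` (vectorized).
#' @param t time, `t >= 0`.
#' @export
mean_type_count <- function(i, t) {
  if (any(i < 1)) stop("i must be >= 1", call. = FALSE)
  out <- exp((i - 1) * log(pmax(t, .Machine$double.xmin)) - lgamma(i))
  out[i == 1] <- 1
  out
}

#' Arrival law of the first type-2 cell
#'
#' In the critical family with all division rates one and a constant
#' mutation rate `nu` (death rate `1 - nu` keeps each type critical), the
#' first type-2 cell arrives before `t` with probability
#' `sqrt(nu) tanh(sqrt(nu) t)`.  For `nu < 1` the law is defective: with
#' probability `1 - sqrt(nu)` no type-2 cell ever appears.  For `nu = 1`
#' (pure birth-mutation) the arrival is certain, with survival function
#' `P(T_2 > t) = 2 / (1 + e^(2t))` and mean `log 2`.
#'
#' @param t time, `t >= 0` (vectorized).
#' @param nu mutation rate in `(0, 1]`.
#' @return `arrival_cdf_two_type()`: `P(T_2 <= t)`.
#' @export
arrival_cdf_two_type <- function(t, nu = 1) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]", call. = FALSE)
  sqrt(nu) * tanh(sqrt(nu) * t)
}

#' @rdname arrival_cdf_two_type
#' @return `arrival_survival_two_type()`: `P(T_2 > t)` for `nu = 1`.
#' @export
arrival_survival_two_type <- function(t) 2 / (1 + exp(2 * t))
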