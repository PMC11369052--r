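#' Extract a probability mass function from a generating function
#'
#' Coefficients of an analytic probability generating function are Cauchy
#' contour integrals, `P_s = (2 pi i)^-1 \oint gf(x) x^(-s-1) dx`.  On the
#' circle `|x| = r < 1` the integral becomes a discrete Fourier average,
#' evaluated here with one FFT over `npoints` equispaced contour nodes:
#' `P_s = r^-s * (1/N) sum_k gf(r w^k) w^(-ks)`.
#'
#' The radius trades aliasing against round-off amplification: the factor
#' `r^-s` magnifies the quadrature round-off, which bounds the usable
#' `s_max` at roughly `15 / |log10 r|` in double precision — the function
#' computes this bound and refuses `s_max` beyond it.  Contours must stay
#' inside the unit disk because the two-type generating function is
#' singular at `x2 = 1`.
#'
#' @param gf function of one (complex) argument, analytic on `|x| <= r`.
#' @param s_max largest coefficient index wanted.
#' @param radius contour radius `r` in `(0, 1)`.
#' @param npoints number of contour nodes `N >= 2 (s_max + 1)`; default
#'   `8 * (s_max + 1)`.
#' @param t time label stored with the result (metadata only).
#' @param zero_tol negative coefficients larger than `-zero_tol` are zeroed
#'   as round-off; more negative values raise an inversion-quality error.
#' @param imag_tol largest tolerated imaginary residue.
#' @return A `bdm_pmf`: list with `s = 0:s_max`, `prob`, the normalization
#'   `deficit` `1 - sum(prob)` (unresolved tail mass), `max_imag`, and
#'   contour metadata.
#' @examples
#' p <- gf_invert(function(x) single_type_gf(x, 1), s_max = 32)
#' p$prob[2]  # P(Z = 1) at t = 1, exactly 1/4
#' @export
gf_invert <- function(gf, s_max, radius = 0.99, npoints = NULL, t = NA_real_,
                      zero_tol = 1e-12, imag_tol = 1e-8) {
  stopifnot(radius > 0, radius < 1, s_max >= 0)
  s_bound <- floor(15 / abs(log10(radius)))
  if (s_max > s_bound)
    stop(sprintf("s_max = %d exceeds the round-off amplification bound %d at radius %g",
                 s_max, s_bound, radius), call. = FALSE)
  if (is.null(npoints)) npoints <- 8L * (s_max + 1L)
  if (npoints < 2L * (s_max + 1L))
    stop("npoints must be at least 2 * (s_max + 1)", call. = FALSE)
  x <- radius * exp(2i * pi * seq(0L, npoints - 1L) / npoints)
  vals <- gf(x)
  co <- fft(vals)[seq_len(s_max + 1L)] / npoints
  amp <- radius^-(0:s_max)
  prob <- Re(co) * amp
  max_imag <- max(abs(Im(co)) * amp)
  if (max_imag > imag_tol)
    stop(sprintf("inversion quality: imaginary residue %.3g exceeds %.3g",
                 max_imag, imag_tol), call. = FALSE)
  if (any(prob < -zero_tol))
    stop(sprintf("inversion quality: negative coefficient %.3g below -%.3g",
                 min(prob), zero_tol), call. = FALSE)
  prob[prob < 0] <- 0
  deficit <- 1 - sum(prob)
  if (deficit < -1e-6)
    stop(sprintf("inversion quality: normalization deficit %.3g < -1e-6", deficit),
         call. = FALSE)
  structure(list(s = 0:s_max, prob = prob, t = t, radius = radius,
                 npoints = npoints, deficit = deficit, max_imag = max_imag,
                 provenance = "gf_inversion"),
            class = "bdm_pmf")
}

#' @export
print.bdm_pmf <- function(x, ...) {
  cat(sprintf("bdm_pmf (%s): s = 0..%d%s, mass %.6f (deficit %.3g)\n",
              x$provenance, max(x$s),
              if (!is.na(x$t)) sprintf(" at t = %g", x$t) else "",
              sum(x$prob), x$deficit))
  invisible(x)
}

#' @export
as.data.frame.bdm_pmf <- function(x, ...) data.frame(s = x$s, prob = x$prob)

#' Joint two-variable coefficient extraction
#'
#' Nested Cauchy contours, one FFT per variable: recovers the joint mass
#' `P_(a,b)` of a bivariate generating function such as the two-type
#' `E(x1^Z1 x2^Z2)`.  Marginals follow by row/column summation.
#'
#' @param gf function of two complex vectors (evaluated elementwise).
#' @param a_max,b_max largest indices wanted.
#' @param radii contour radii for the two variables.
#' @param npoints node counts; default `4 * (max_index + 1)` per axis.
#' @inheritParams gf_invert
#' @return A `bdm_pmf2`: list with matrix `prob` (`a` in rows starting at
#'   0, `b` in columns), `deficit`, `max_imag`, metadata.
#' @export
gf_invert2 <- function(gf, a_max, b_max, radii = c(0.99, 0.99),
                       npoints = NULL, t = NA_real_,
                       zero_tol = 1e-12, imag_tol = 1e-8) {
  stopifnot(all(radii > 0), all(radii < 1))
  s_bound <- floor(15 / abs(log10(min(radii))))
  if (a_max + b_max > s_bound)
    stop(sprintf("a_max + b_max = %d exceeds the amplification bound %d",
                 a_max + b_max, s_bound), call. = FALSE)
  if (is.null(npoints)) npoints <- 4L * (c(a_max, b_max) + 1L)
  stopifnot(npoints[1] >= 2L * (a_max + 1L), npoints[2] >= 2L * (b_max + 1L))
  n1 <- npoints[1]; n2 <- npoints[2]
  x1 <- radii[1] * exp(2i * pi * seq(0L, n1 - 1L) / n1)
  x2 <- radii[2] * exp(2i * pi * seq(0L, n2 - 1L) / n2)
  V <- matrix(gf(rep(x1, times = n2), rep(x2, each = n1)), n1, n2)
  co <- fft(V)[seq_len(a_max + 1L), seq_len(b_max + 1L), drop = FALSE] / (n1 * n2)
  amp <- outer(radii[1]^-(0:a_max), radii[2]^-(0:b_max))
  prob <- Re(co) * amp
  max_imag <- max(abs(Im(co)) * amp)
  if (max_imag > imag_tol)
    stop(sprintf("inversion quality: imaginary residue %.3g exceeds %.3g",
                 max_imag, imag_tol), call. = FALSE)
  if (any(prob < -zero_tol))
    stop(sprintf("inversion quality: negative coefficient %.3g below -%.3g",
                 min(prob), zero_tol), call. = FALSE)
  prob[prob < 0] <- 0
  structure(list(a = 0:a_max, b = 0:b_max, prob = prob, t = t,
                 radii = radii, npoints = c(n1, n2),
                 deficit = 1 - sum(prob), max_imag = max_imag,
                 provenance = "gf_inversion"),
            class = "bdm_pmf2")
}

#' Number distributions of the two-type process by contour inversion
#'
#' Convenience wrappers binding [gf_invert()] to the exact two-type
#' generating function: `pmf_type2()` extracts the marginal mass function
#' of the number of type-2 cells (generating function evaluated at
#' `x1 = 1`), `pmf_total_two_type()` that of the total population
#' (`x1 = x2 = x`), both started from a single type-1 cell.  These are the
#' distributions whose large-time limit develops the algebraic
#' `s^(-3/2)` tail.
#'
#' @param t time, `t > 0`.
#' @param s_max largest count wanted.
#' @inheritParams gf_invert
#' @param ... passed on to [gf_invert()].
#' @return A `bdm_pmf`.
#' @export
pmf_type2 <- function(t, s_max, radius = 0.99, ...) {
  stopifnot(t > 0)
  gf_invert(function(x) two_type_gf(1, x, t), s_max = s_max, radius = radius,
            t = t, ...)
}

#' @rdname pmf_type2
#' @export
pmf_total_two_type <- function(t, s_max, radius = 0.99, ...) {
  stopifnot(t > 0)
  gf_invert(function(x) two_type_gf(x, x, t), s_max = s_max, radius = radius,
            t = t, ...)
}
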