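# Exponentially scaled modified Bessel functions of complex argument.
#
# Base R's besselI/besselK are real-only, and the two-type generating
# function must be evaluated on complex FFT contours.  All arguments
# arising there have |arg z| <= pi/4 and Re z >= 1 (z = 2*sqrt(w) with
# Re w >= 1/2), where the scaled integral representations below are
# evaluated to near machine precision by trapezoid/midpoint rules:
# both integrands are analytic and either periodic (I) or exponentially
# decaying with all odd derivatives vanishing at 0 (K), so the rules
# converge spectrally.
#
#   Ie_nu(z) = I_nu(z) e^{-z} = (1/pi) Int_0^pi e^{z(cos th - 1)} cos(nu th) dth
#   Ke_nu(z) = K_nu(z) e^{+z} =        Int_0^inf e^{-z(cosh u - 1)} cosh(nu u) du
#
# The scaling keeps every factor bounded: Re(z(cos th - 1)) <= 0 whenever
# Re z >= 0.  Node counts cover |z| up to ~500, beyond the range needed by
# the contour evaluations (real large-argument work uses base R's scaled
# Bessel functions instead).

besselIe_c <- function(z, nu, nodes = 800L) {
  th <- (seq_len(nodes) - 0.5) * (pi / nodes)
  colSums(exp(outer(cos(th) - 1, z)) * cos(nu * th)) / nodes
}

besselKe_c <- function(z, nu, h = 0.02, upper = 6) {
  u <- seq(0, upper, by = h)
  w <- rep(h, length(u))
  w[1] <- h / 2
  colSums(exp(-outer(cosh(u) - 1, z)) * (cosh(nu * u) * w))
}
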