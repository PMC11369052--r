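test_that("single-type closed forms: survival, pmf, generating function", {
  expect_equal(single_type_survival(0), 1)
  expect_equal(single_type_survival(10), 1 / 11)
  expect_lt(single_type_survival(1e12), 1e-11)
  expect_error(single_type_survival(-1), "non-negative")

  expect_equal(single_type_pmf(1, 1), 1 / 4)
  for (t in c(0.5, 1, 5))
    expect_equal(sum(single_type_pmf(0:2000, t)), 1, tolerance = 1e-10)
  # conditional law is geometric with success probability 1/(1+t)
  t <- 3
  cond <- single_type_pmf(1:50, t) / single_type_survival(t)
  expect_equal(cond, stats::dgeom(0:49, 1 / (1 + t)), tolerance = 1e-12)

  expect_equal(single_type_gf(1, 7), 1)
  expect_equal(single_type_gf(0, 7), single_type_pmf(0, 7))
  h <- 1e-6
  deriv <- (single_type_gf(1, 2) - single_type_gf(1 - h, 2)) / h
  expect_equal(deriv, 1, tolerance = 1e-5)  # mean stays 1
})

test_that("Yule total population: geometric mass and exponential mean", {
  expect_equal(yule_pmf(1, 2), exp(-2))
  expect_equal(sum(yule_pmf(1:5000, 2)), 1, tolerance = 1e-10)
  expect_equal(yule_mean(3), exp(3))
  expect_equal(sum((1:50000) * yule_pmf(1:50000, 3)), exp(3), tolerance = 1e-6)
})

test_that("two-type Bessel survival: initial value, decay and ODE agreement", {
  expect_equal(two_type_survival(0), 1)
  expect_true(all(diff(two_type_survival(seq(0, 100, 1))) < 0))
  # (1+t)^(1/2)-scaled value tends to 1
  expect_lt(abs(two_type_survival(1e6) * sqrt(1 + 1e6) - 1), 1e-3)
  # numerically stable far beyond the naive overflow point
  expect_true(is.finite(two_type_survival(1e8)))
  expect_lt(abs(two_type_survival(1e8) * sqrt(1 + 1e8) - 1), 1e-4)

  tt <- c(0, 10^seq(-2, 4, 0.25))
  sol <- solve_survival(2, tt)
  expect_lt(max(abs(sol$values[, 1] - two_type_survival(tt))), 1e-8)
})

test_that("two-type generating function: initial condition, survival, bounds", {
  # at t = 0 the generating function is x1
  x1 <- c(0.3, -0.2, 0.5 + 0.4i)
  x2 <- c(-0.7, 0.9, 0.1 - 0.6i)
  expect_lt(max(Mod(two_type_gf(x1, x2, 0) - x1)), 1e-10)

  for (t in c(0.5, 5, 50))
    expect_lt(Mod(two_type_gf(0, 0, t) - (1 - two_type_survival(t))), 1e-10)

  expect_error(two_type_gf(0.5, 1, 3), "singular")

  # probability generating function bound on the closed unit polydisk
  th <- seq(0, 2 * pi, length.out = 17)
  grid <- expand.grid(r1 = c(0.3, 0.95), r2 = c(0.3, 0.95),
                      th1 = th, th2 = th)
  z <- two_type_gf(grid$r1 * exp(1i * grid$th1),
                   grid$r2 * exp(1i * grid$th2), 2)
  expect_true(all(Mod(z) <= 1 + 1e-10))
})

test_that("the gf solves the Riccati equation (five-point residual check)", {
  h <- 1e-2
  for (x2 in c(-0.5, 0, 0.5, 0.9)) {
    for (t in c(0.5, 2, 10)) {
      u <- function(tt) 1 - Re(two_type_gf(0.2, x2, tt))  # u = 1 - Z_{1,2}
      du <- (u(t - 2 * h) - 8 * u(t - h) + 8 * u(t + h) - u(t + 2 * h)) / (12 * h)
      z22 <- Re(single_type_gf(x2, t))                    # index-shifted single type
      residual <- du - ((1 - z22) - u(t)^2)
      expect_lt(abs(residual), 1e-8)
    }
  }
})

test_that("mean type counts and their exponential sum", {
  expect_equal(mean_type_count(1, 0), 1)
  expect_equal(mean_type_count(1, 17), 1)
  expect_equal(mean_type_count(3, 2), 2)
  expect_equal(sum(mean_type_count(1:200, 3)), exp(3), tolerance = 1e-12)
})

test_that("type-2 arrival law: tanh form, defective limit, mean log 2", {
  expect_equal(arrival_cdf_two_type(0), 0)
  tt <- seq(0, 10, 0.1)
  expect_equal(arrival_cdf_two_type(tt), tanh(tt))
  expect_equal(arrival_cdf_two_type(tt, nu = 0.25), 0.5 * tanh(0.5 * tt))
  expect_equal(arrival_cdf_two_type(1e3, nu = 0.25), 0.5, tolerance = 1e-12)
  expect_equal(arrival_survival_two_type(tt), 1 - tanh(tt), tolerance = 1e-12)
  expect_equal(integrate(function(t) 1 - arrival_cdf_two_type(t), 0, Inf)$value,
               log(2), tolerance = 1e-8)
  expect_error(arrival_cdf_two_type(1, nu = 1.5), "in \\(0, 1\\]")
})

test_that("complex-argument scaled Bessel quadrature matches base R on the real axis", {
  z <- c(1, 2, 5, 14, 40, 120, 300)
  for (nu in 0:1) {
    expect_equal(Re(critbdm:::besselIe_c(z, nu)),
                 besselI(z, nu, expon.scaled = TRUE), tolerance = 1e-13)
    expect_equal(Re(critbdm:::besselKe_c(z, nu)),
                 besselK(z, nu, expon.scaled = TRUE), tolerance = 1e-13)
  }
  # Wronskian identity off the real axis
  zc <- complex(real = c(2, 10, 30, 60), imaginary = c(1, -6, 20, -35))
  w <- critbdm:::besselIe_c(zc, 0) * critbdm:::besselKe_c(zc, 1) +
    critbdm:::besselIe_c(zc, 1) * critbdm:::besselKe_c(zc, 0)
  expect_lt(max(Mod(w - 1 / zc)), 1e-13)
})
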