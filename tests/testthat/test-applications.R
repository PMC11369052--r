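test_that("Shannon index: closed-form two-phase replacement fixture", {
  # type 1 linearly replaced by type 2: H rises to log 2 at the midpoint
  # and returns to 0, exactly -p log p - (1-p) log(1-p)
  tt <- seq(0, 1, 0.05)
  counts <- cbind(100 * (1 - tt), 100 * tt)
  tr <- make_fixture_trajectory(tt, counts, spec = simple_bdm(2))
  h <- shannon_index(tr)$shannon
  p <- tt[2:20]
  expect_equal(h[2:20], -(p * log(p) + (1 - p) * log(1 - p)), tolerance = 1e-12)
  expect_equal(h[1], 0)   # single type present
  expect_equal(h[21], 0)
  expect_equal(max(h), log(2), tolerance = 1e-12)
  # equal proportions of k types give log k; base option rescales
  tr4 <- make_fixture_trajectory(c(0, 1), rbind(c(5, 5, 5, 5), c(5, 5, 5, 5)),
                                 spec = simple_bdm(4))
  expect_equal(shannon_index(tr4)$shannon, rep(log(4), 2))
  expect_equal(shannon_index(tr4, base = 2)$shannon, rep(2, 2))
  # extinct population: H is missing
  tr0 <- make_fixture_trajectory(c(0, 1), rbind(c(1, 0), c(0, 0)),
                                 spec = simple_bdm(2))
  expect_true(is.na(shannon_index(tr0)$shannon[2]))
})

test_that("ensemble Shannon diversity peaks then declines in a 4-type run", {
  trs <- simulate(simple_bdm(4), nsim = 150, seed = 14, t_max = 30,
                  times = seq(0, 30, 0.5))
  h <- shannon_index(trs)
  peak <- which.max(h$shannon)
  expect_gt(peak, 1)                       # interior peak, H(0) = 0
  expect_lt(h$time[peak], 20)
  expect_lt(h$shannon[length(h$shannon)], 0.6 * max(h$shannon))
  expect_equal(h$shannon[1], 0)
})

test_that("expected number of types: bounds, composition and shape", {
  tt <- seq(0, 60, 0.5)
  k1 <- expected_types(1, tt)
  expect_equal(k1$k_types, single_type_survival(tt), tolerance = 1e-8)

  k2 <- expected_types(2, tt)
  q2 <- solve_presence(2, tt)$values[, 1]
  expect_equal(k2$k_types, single_type_survival(tt) + q2, tolerance = 1e-8)
  expect_true(all(q2 <= solve_survival(2, tt)$values[, 1] + 1e-10))

  for (n in 2:4) {
    k <- expected_types(n, tt)
    expect_equal(k$k_types[1], 1)          # only type 1 at t = 0
    expect_true(all(k$k_types <= n + 1e-9))
    # single interior maximum: increments change sign exactly once
    sgn <- sign(diff(k$k_types))
    expect_equal(sum(diff(sgn[sgn != 0]) != 0), 1)
    expect_gt(which.max(k$k_types), 1)
  }
})

test_that("K_n decays like t^-chi_n at large times", {
  tt <- c(0, 10^seq(0, 7, 0.5))
  for (n in 2:3) {
    k <- expected_types(n, tt)$k_types
    i1 <- which(tt == 1e5); i2 <- which(tt == 1e7)
    slope <- (log(k[i2]) - log(k[i1])) / (log(1e7) - log(1e5))
    # subleading components decay a factor t^(-chi_n) slower, so the finite-t
    # slope carries a bias of a few percent at these horizons
    expect_lt(abs(slope + chi_exponent(n)) / chi_exponent(n), 0.05)
  }
})

test_that("survival after t generations and its inverse are consistent", {
  expect_equal(survival_after_generations(1, 10), 1 / 11)
  expect_equal(survival_after_generations(2, 10), two_type_survival(10))
  expect_equal(survival_after_generations(3, c(5, 50)),
               solve_survival(3, c(0, 5, 50))$values[2:3, 1], tolerance = 1e-9)
  # the expansion fast path is close at large t
  expect_lt(abs(survival_after_generations(2, 1e4, method = "expansion") /
                  two_type_survival(1e4) - 1), 1e-3)

  expect_equal(as.numeric(generations_to_survival(1, 0.1)), 9, tolerance = 1e-6)
  t2 <- generations_to_survival(2, 0.1)
  expect_gte(as.numeric(t2), 100)          # about 100 generations for n = 2
  expect_lt(as.numeric(t2), 110)
  expect_lt(abs(attr(t2, "expansion") / as.numeric(t2) - 1), 0.05)
  t5 <- as.numeric(generations_to_survival(5, 0.5))
  expect_gt(t5, 1e4); expect_lt(t5, 1e6)   # order 1e5 generations
  expect_error(generations_to_survival(2, 1.2), "in \\(0, 1\\)")
})

test_that("expected colony size interpolates the Yule curve and its plateau", {
  expect_equal(as.numeric(expected_colony_size(1, c(1, 20))), c(1, 1))
  expect_equal(as.numeric(expected_colony_size(2, 20)), 21)
  big <- expected_colony_size(60, 20)
  expect_equal(as.numeric(big), exp(20), tolerance = 1e-8)
  expect_equal(attr(big, "yule_reference"), exp(20))
  # monotone in n at fixed t
  sizes <- vapply(1:10, function(n) as.numeric(expected_colony_size(n, 20)),
                  numeric(1))
  expect_true(all(diff(sizes) > 0))
})

test_that("the command line interface writes well-formed tables", {
  out <- file.path(tempdir(), "cli-test")
  dir.create(out, showWarnings = FALSE)

  expect_equal(bdm_cli(c("survival", "--n", "3", "--tmax", "1e4",
                         "--grid", "log:100", "--out", out)), 0L)
  surv <- read.csv(file.path(out, "survival.csv"))
  expect_equal(nrow(surv), 300)  # 100 grid points x 3 components
  s1 <- surv$value[surv$component == 1]
  expect_true(all(diff(s1) <= 1e-12))

  cfg <- file.path(out, "simple2.json")
  write_bdm_config(simple_bdm(2), cfg, t_max = 5, reps = 50, seed = 3)
  expect_equal(bdm_cli(c("simulate", "--config", cfg, "--out", out)), 0L)
  expect_true(file.exists(file.path(out, "counts.csv")))
  a <- read.csv(file.path(out, "counts.csv"))
  expect_equal(bdm_cli(c("simulate", "--config", cfg, "--out", out)), 0L)
  b <- read.csv(file.path(out, "counts.csv"))
  expect_identical(a, b)        # determinism under a fixed seed

  expect_equal(bdm_cli(c("arrival", "--n", "2", "--nu", "1", "--tmax", "5",
                         "--out", out)), 0L)
  arr <- read.csv(file.path(out, "arrival.csv"))
  g1 <- arr$value[arr$component == 1]
  expect_lt(max(abs(g1 - tanh(arr$time[arr$component == 1]))), 1e-6)

  expect_equal(bdm_cli(c("pmf", "--t", "2", "--which", "type2",
                         "--smax", "64", "--out", out)), 0L)
  pm <- read.csv(file.path(out, "pmf_type2.csv"))
  expect_equal(sum(pm$prob), 1, tolerance = 1e-6)

  expect_equal(bdm_cli(character(0)), 1L)
  expect_equal(bdm_cli(c("unknown-subcommand")), 1L)
  expect_equal(bdm_cli(c("survival", "--n")), 1L)  # dangling flag
})
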