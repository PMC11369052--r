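test_that("degenerate initial conditions return immediately", {
  spec <- bdm_process(c(1, 1), c(0, 1), c(1, 0), initial = c(0, 0))
  tr <- simulate(spec, seed = 1, t_max = 5, record = "events")
  expect_equal(tr$n_events, 0)
  expect_equal(tr$status, "extinct")
  expect_true(all(is.na(tr$arrivals)))
  expect_true(all(is.na(tr$extinctions)))
})

test_that("the same seed reproduces trajectories and ensembles exactly", {
  a <- simulate(simple_bdm(3), seed = 99, t_max = 8, record = "events")
  b <- simulate(simple_bdm(3), seed = 99, t_max = 8, record = "events")
  expect_identical(a$counts, b$counts)
  expect_identical(a$times, b$times)
  c <- simulate(simple_bdm(3), seed = 100, t_max = 8, record = "events")
  expect_false(identical(a$times, c$times))

  e1 <- bdm_ensemble(simple_bdm(2), times = c(0, 1, 2), reps = 50, seed = 7)
  e2 <- bdm_ensemble(simple_bdm(2), times = c(0, 1, 2), reps = 50, seed = 7)
  expect_identical(e1$mean_counts, e2$mean_counts)
  expect_identical(e1$arrivals, e2$arrivals)
})

test_that("trajectory invariants hold: T_1 = 0, T_k <= E_k, counts >= 0", {
  # until-extinction runs of a critical process have heavy-tailed length,
  # so a capped run (partial trajectory) is an acceptable outcome here
  for (seed in 1:10) {
    tr <- tryCatch(
      simulate(simple_bdm(4), seed = seed, t_max = Inf, record = "events",
               max_events = 1e6, max_cells = 1e6),
      bdm_capped_run = function(e) e$trajectory)
    expect_equal(unname(tr$arrivals[1]), 0)
    expect_true(all(tr$counts >= 0))
    both <- !is.na(tr$arrivals) & !is.na(tr$extinctions)
    expect_true(all(tr$arrivals[both] <= tr$extinctions[both]))
    expect_true(tr$status %in% c("extinct", "capped"))
    if (tr$status == "extinct")
      expect_true(all(tr$counts[nrow(tr$counts), ] == 0))
  }
})

test_that("exceeding the caps raises a classed error carrying the partial run", {
  spec <- bdm_process(1, 1, 0, initial = 50)
  err <- tryCatch(
    simulate(spec, seed = 1, t_max = Inf, record = "events", max_events = 10),
    bdm_capped_run = function(e) e)
  expect_s3_class(err, "bdm_capped_run")
  expect_s3_class(err$trajectory, "bdm_trajectory")
  expect_equal(err$trajectory$n_events, 10)
})

test_that("single-type survival and mean match the closed forms", {
  es <- bdm_ensemble(simple_bdm(1), times = c(0, 2, 4), reps = 20000, seed = 5,
                     conf_level = 0.95)
  # fraction alive at t = 4 ~ 1/5, within 4 Wilson half-widths
  expect_lt(abs(es$survival_any$estimate[3] - 0.2),
            4 * es$survival_any$halfwidth[3])
  # criticality conserves the mean at 1
  expect_lt(abs(es$mean_counts[3, 1] - 1), 4 * es$se_counts[3, 1])
  expect_true(all(es$survival_last$estimate <= es$survival_any$estimate + 1e-12))
})

test_that("mean counts follow t^(i-1)/(i-1)! within 4 standard errors", {
  es <- bdm_ensemble(simple_bdm(4), times = c(0, 1, 2, 5), reps = 100000,
                     seed = 12)
  for (i in 1:4)
    for (g in 2:4) {
      expected <- mean_type_count(i, es$times[g])
      expect_lt(abs(es$mean_counts[g, i] - expected),
                4 * max(es$se_counts[g, i], 1e-12))
    }
})

test_that("a large-n process proxies the Yule total population", {
  es <- bdm_ensemble(simple_bdm(30), times = c(0, 3), reps = 20000, seed = 8)
  total <- sum(es$mean_counts[2, ])
  se_total <- sqrt(sum(es$se_counts[2, ]^2))
  expect_lt(abs(total - yule_mean(3)), 4 * se_total * 3)
})

test_that("simulated survival curves agree with the ODE solutions", {
  tt <- c(0, 1, 2, 5, 10)
  for (n in c(2, 4)) {
    es <- bdm_ensemble(simple_bdm(n), times = tt, reps = 20000, seed = n)
    sol <- solve_survival(n, tt)
    expect_true(all(abs(es$survival_any$estimate - sol$values[, 1]) <=
                      4 * pmax(es$survival_any$halfwidth, 1e-4)))
    qq <- solve_presence(n, tt)
    expect_true(all(abs(es$survival_last$estimate - qq$values[, 1]) <=
                      4 * pmax(es$survival_last$halfwidth, 1e-4)))
  }
})

test_that("for pure birth-mutation, E_n > t coincides with whole-system survival", {
  # replicate-by-replicate equivalence of the two events
  es <- bdm_ensemble(simple_bdm(3), times = c(0, 2, 5, 10), reps = 2000,
                     seed = 31, keep_counts = TRUE)
  e3 <- es$extinctions[, 3]
  cens <- es$censored[, 3]
  for (g in 2:4) {
    t <- es$times[g]
    alive <- es$counts_total[, g] > 0
    # E_3 > t: censored at t_max, or extinct later than t; never-arrived => FALSE
    en_gt <- (cens | (!is.na(e3) & e3 > t))
    expect_identical(unname(alive), unname(en_gt))
  }
})

test_that("the type-2 extinction-time tail has exponent about -1/2", {
  tt <- c(0, 10, 100)
  es <- bdm_ensemble(simple_bdm(2), times = tt, reps = 5000, seed = 17,
                     keep_counts = TRUE)
  p_surv <- colMeans(es$counts_total[, 2:3] > 0)
  slope <- (log(p_surv[2]) - log(p_surv[1])) / (log(100) - log(10))
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("mean arrival time of the first type-2 cell is log 2", {
  es <- bdm_ensemble(simple_bdm(2), times = 0, t_max = 50, reps = 20000,
                     seed = 21, stop_on_arrival = TRUE)
  t2 <- es$arrivals[, 2]
  expect_false(anyNA(t2))
  expect_lt(abs(mean(t2) - log(2)), 4 * sd(t2) / sqrt(length(t2)))
})

test_that("empirical pmf conditioned on survival is geometric for one type", {
  es <- bdm_ensemble(simple_bdm(1), times = c(0, 1), reps = 20000, seed = 2,
                     keep_counts = TRUE)
  p <- empirical_pmf(es, t = 1, which = "last", conditional = TRUE)
  expect_equal(p$prob[1], 0)  # conditioned away
  geo <- 0.5^(1:8)
  expect_true(all(abs(p$prob[2:9] - geo) < 0.02))

  # unconditional mass at zero is the complement of survival
  pu <- empirical_pmf(es, t = 1, which = "total")
  es_surv <- es$survival_any$estimate[2]
  expect_equal(pu$prob[1], 1 - es_surv, tolerance = 1e-12)
  expect_error(empirical_pmf(es, t = 0.37), "not on the recorded grid")
})

test_that("scaled type-2 numbers match the hypergeometric scaling curve", {
  t <- 20
  es <- bdm_ensemble(simple_bdm(2), times = c(0, t), reps = 30000, seed = 4,
                     keep_counts = TRUE)
  p <- empirical_pmf(es, t = t, which = "last", conditional = FALSE)
  q <- mean(es$counts_last[, 2] > 0)
  # bulk bins y = s/t in [0.5, 4]: empirical t^(1+chi) P_s / chi vs F(3/2;2;-y)
  for (y in c(0.5, 1, 2, 4)) {
    s <- round(y * t) + (-2:2)         # average 5 adjacent masses
    emp <- mean(p$prob[s + 1])
    theo <- mean(pmf_scaling(2, s, t))
    expect_lt(abs(emp / theo - 1), 0.25)
  }
  expect_gt(q, 0.15)  # sanity: enough surviving mass for the comparison
})
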