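test_that("follow-up statistic matches hand counts on a toy cohort", {
  co <- toy_cohort(c(1, 2, 3, 4, 5), c(1, 1, 1, 0, 0))
  r <- mz_followup_test(co)
  expect_equal(r$t_event_max, 3)
  expect_equal(r$t_obs_max, 5)
  expect_equal(r$delta_n, 2)
  expect_equal(r$window, c(1, 3))
  expect_equal(r$N_n, 2)        # events at 2 and 3; (1, 3] is open-left
  expect_equal(r$q_n, 0.4)
  expect_false(r$degenerate)
})

test_that("window arithmetic on the registry's printed time pair", {
  co <- toy_cohort(c(11.72, 16.78), c(1, 0))
  r <- mz_followup_test(co)
  expect_equal(r$delta_n, 5.06, tolerance = 1e-8)
  expect_equal(r$window, c(6.66, 11.72), tolerance = 1e-8)
})

test_that("a last observation that is an event degenerates the window", {
  co <- toy_cohort(c(1, 2, 3), c(1, 1, 1))
  r <- mz_followup_test(co)
  expect_true(r$degenerate)
  expect_equal(r$q_n, 0)
  expect_equal(r$N_n, 0)
  expect_error(mz_followup_test(toy_cohort(c(1, 2), c(0, 0))), "no events")
})

test_that("N_n equals a brute-force count and ignores censored times", {
  for (seed in 11:16) {
    co <- random_cohort(40, seed)
    r <- mz_followup_test(co)
    t <- co$time_years; d <- co$event
    lo <- 2 * r$t_event_max - r$t_obs_max
    expect_equal(r$N_n,
                 sum(d == 1 & t > lo & t <= r$t_event_max & !r$degenerate))
  }
  # censored observations inside the window do not change the count
  co <- toy_cohort(c(1, 2, 3, 4, 5), c(1, 1, 1, 0, 0))
  co2 <- toy_cohort(c(1, 2, 2.5, 2.7, 3, 4, 5),
                    c(1, 1, 0, 0, 1, 0, 0))
  expect_equal(mz_followup_test(co2)$N_n, mz_followup_test(co)$N_n)
})

test_that("presence statistic is the KM CDF at the largest observed time", {
  for (seed in 3:6) {
    co <- random_cohort(60, seed)
    km <- km_estimate(co)
    p <- mz_cure_presence_test(co, "exponential", reps = 100)$p_hat
    expect_equal(p, 1 - survival_at(km, attr(km, "t_max_obs"))$estimate)
  }
  # last observation an event with the curve reaching 0: CDF = 1
  co <- toy_cohort(c(1, 2), c(1, 1))
  expect_equal(mz_cure_presence_test(co, reps = 100)$p_hat, 1)
  # all censored: degenerate
  r0 <- mz_cure_presence_test(toy_cohort(c(1, 2), c(0, 0)))
  expect_equal(r0$p_hat, 0)
  expect_false(r0$reject_h0)
})

test_that("bundled critical values are returned exactly in table mode", {
  expect_identical(
    mz_critical_value(1000, "exponential", 0.05, "p_hat", "table"), 0.940)
  expect_identical(
    mz_critical_value(1000, "uniform", 0.05, "p_hat", "table"), 0.960)
  # published limiting behaviour for samples beyond the tabled size
  expect_identical(
    mz_critical_value(5000, "exponential", 0.05, "p_hat", "table"), 1)
  expect_error(
    mz_critical_value(200, "exponential", 0.05, "p_hat", "table"),
    "simulation is disabled")
  expect_warning(
    v <- mz_critical_value(200, "exponential", 0.05, "p_hat", "auto",
                           reps = 100, seed = 2),
    "falling back")
  expect_true(v >= 0 && v <= 1)
})

test_that("null simulation is reproducible and bounded", {
  a <- simulate_mz_null(200, "uniform", reps = 150, seed = 4, B = 2)
  b <- simulate_mz_null(200, "uniform", reps = 150, seed = 4, B = 2)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0 & a$values <= 1))
  qn <- simulate_mz_null(200, "exponential", reps = 150, seed = 4,
                         statistic = "q_n")
  expect_true(all(qn$values >= 0 & qn$values <= 1))
  expect_error(simulate_mz_null(100, "uniform", reps = 50), "at least 100")
})

test_that("simulation reconstructs the bundled exponential critical value", {
  # independent Monte-Carlo route to the published 0.940 entry
  null <- simulate_mz_null(1000, "exponential", reps = 600, seed = 12,
                           mu = 1)
  crit <- unname(quantile(null$values, 0.05))
  expect_lt(abs(crit - 0.940), 0.02)
})

test_that("a no-cure cohort with long follow-up drives the CDF towards 1", {
  cfg <- paper_default_config(n_subjects = 10000)
  cfg$cure$intercept <- 10          # pi ~ 0: everyone susceptible
  cfg$censoring <- list(kind = "uniform", upper = 60)
  cfg$study_window_years <- 60
  co <- generate_cohort(cfg, seed = 8)
  r <- mz_cure_presence_test(co, "uniform", reps = 100, seed = 1)
  expect_gt(r$p_hat, 0.95)
})

test_that("default registry-like cohort shows a clear cured fraction", {
  co <- generate_cohort(paper_default_config(), seed = 23)
  r <- mz_cure_presence_test(co, "exponential", alpha = 0.05,
                             reps = 150, seed = 2)
  expect_lt(abs(r$p_hat - 0.51), 0.04)
  expect_true(r$reject_h0)
  f <- mz_followup_test(co, censor_model = "exponential", reps = 150,
                        seed = 2)
  expect_true(f$sufficient)
})
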