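test_that("generation is deterministic given the seed", {
  cfg <- paper_default_config(n_subjects = 300)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a$time_years, c$time_years))
})

test_that("all-cured limit yields a fully censored cohort", {
  cfg <- paper_default_config(n_subjects = 500)
  cfg$cure$intercept <- -20  # pi = exp(-exp(-20)) = 1 to machine precision
  co <- generate_cohort(cfg, seed = 1)
  expect_equal(sum(co$event), 0)
  expect_true(all(co$.cured))
  expect_true(all(is.infinite(co$.latent_time)))
})

test_that("latent-cured subjects never show an observed event", {
  co <- generate_cohort(paper_default_config(n_subjects = 2000), seed = 3)
  expect_true(all(co$event[co$.cured] == 0))
  expect_true(all(is.infinite(co$.latent_time[co$.cured])))
  expect_true(all(is.finite(co$.latent_time[!co$.cured])))
})

test_that("event fraction matches a numerical-integration oracle", {
  cfg <- paper_default_config(n_subjects = 50000)
  co <- generate_cohort(cfg, seed = 17)
  # oracle: P(event) = (1 - pi) * E[F_u(C)], by quadrature over the
  # truncated-exponential censoring law, independent of the sampler
  pi0 <- exp(-exp(cfg$cure$intercept))
  k <- cfg$latency$shape
  lam <- cfg$latency$scale
  tau <- cfg$latency$truncation
  W <- cfg$study_window_years
  mu <- cfg$censoring$rate
  Sw <- function(t) exp(-(t / lam)^k)
  Fu <- function(t) pmin((1 - Sw(t)) / (1 - Sw(tau)), 1)
  integrand <- function(c) Fu(c) * mu * exp(-mu * c)
  p_event_oracle <- (1 - pi0) *
    (stats::integrate(integrand, 0, W, rel.tol = 1e-9)$value +
       exp(-mu * W) * Fu(W))
  mc_se <- sqrt(p_event_oracle * (1 - p_event_oracle) / nrow(co))
  expect_lt(abs(mean(co$event) - p_event_oracle), 4 * mc_se)
})

test_that("cohorts are exchangeable under subject reordering", {
  co <- generate_cohort(paper_default_config(n_subjects = 800), seed = 2)
  set.seed(9)
  perm <- sample(nrow(co))
  co2 <- as_cohort(as.data.frame(co)[perm, , drop = FALSE],
                   schema = attr(co, "schema"))
  expect_equal(median_survival(km_estimate(co2)),
               median_survival(km_estimate(co)))
  expect_equal(mz_followup_test(co2)$q_n, mz_followup_test(co)$q_n)
  expect_equal(cohort_summary(co2)$pct_event, cohort_summary(co)$pct_event)
})

test_that("categorization follows the clinical boundary conventions", {
  vals <- c(22, 39.999, 40, 59.999, 60, 85)
  co <- toy_cohort(rep(1, 6), rep(0, 6), age = vals,
                   calcium = c(7, 8.199, 8.2, 10.2, 10.201, 12),
                   ldl = c(50, 99.99, 100, 140, 140.0001, 200))
  cc <- apply_categorization(co)
  expect_equal(as.character(cc$age_cat),
               c("20-40", "20-40", "40-60", "40-60", ">60", ">60"))
  expect_equal(as.character(cc$calcium_cat),
               c("<8.2", "<8.2", "8.2-10.2", "8.2-10.2", ">10.2", ">10.2"))
  expect_equal(as.character(cc$ldl_cat),
               c("<100", "<100", "100-140", "100-140", ">140", ">140"))
  # reference level is the lowest interval; continuous columns retained
  sch <- attr(cc, "schema")
  expect_equal(sch$age_cat$reference, "20-40")
  expect_true(all(c("age", "calcium", "ldl") %in% names(cc)))
})

test_that("categorization warns on empty categories, rejects bad input", {
  co <- toy_cohort(c(1, 2), c(0, 1), age = c(30, 35))
  expect_warning(apply_categorization(co, list(
    age = list(cuts = c(40, 60), right_closed = c(FALSE, FALSE),
               labels = c("20-40", "40-60", ">60")))),
    "empty")
  co2 <- toy_cohort(c(1, 2), c(0, 1), sex = c("m", "f"))
  expect_error(apply_categorization(co2, list(
    sex = list(cuts = 1, labels = c("a", "b")))), "non-numeric")
  expect_error(apply_categorization(co, list(
    age = list(cuts = c(60, 40), labels = c("a", "b", "c")))),
    "increasing")
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(0), "positive integer")
  expect_error(generator_config(10, study_window_years = -1), "positive")
  expect_error(generator_config(10,
    covariates = list(x = list(kind = "categorical",
                               labels = c("a", "b"), probs = c(0.6, 0.6)))),
    "sum to 1")
  expect_error(generator_config(10,
    latency = list(shape = -1, scale = 1)), "strictly positive")
  expect_error(generator_config(10,
    censoring = list(kind = "exponential", rate = NULL)), "rate")
  expect_error(generator_config(10,
    cure = list(link = "cloglog", intercept = 0, coef = c(nope = 1))),
    "unknown covariate")
})

test_that("calibration hits targets and is idempotent", {
  cfg <- paper_default_config()
  targets <- list(cure_fraction = 0.49, median_survival_years = 9.98,
                  censored_fraction = 0.7166)
  cal <- calibrate_generator(cfg, targets, n_sim = 150000L)
  ach <- attr(cal, "achieved")
  expect_lt(abs(ach$cure_fraction - 0.49), 0.01)
  expect_lt(abs(ach$median_survival_years - 9.98), 0.25)
  expect_lt(abs(ach$censored_fraction - 0.7166), 0.01)
  # recalibrating the already-calibrated config barely moves the scalars
  cal2 <- calibrate_generator(cal, targets, n_sim = 150000L)
  expect_lt(abs(cal2$latency$scale - cal$latency$scale), 0.25)
  expect_lt(abs(cal2$censoring$rate - cal$censoring$rate), 0.01)
  expect_lt(abs(cal2$cure$intercept - cal$cure$intercept), 0.02)
})

test_that("calibration reports infeasible targets", {
  cfg <- paper_default_config(n_subjects = 100)
  expect_error(
    calibrate_generator(cfg, list(censored_fraction = 2)), "in \\(0,1\\)")
  expect_error(
    calibrate_generator(cfg, list(nonsense = 1)), "at least one|unknown")
  cfg$censoring <- list(kind = "administrative")
  expect_error(
    calibrate_generator(cfg, list(censored_fraction = 0.7)),
    "administrative")
})
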