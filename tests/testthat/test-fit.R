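# Fit-like object with known parameters, for exercising the prediction and
# transform machinery without an optimizer in the loop.
manual_fit <- function(family, par, spline = NULL, link = "cloglog") {
  spec <- cure_model_spec(family, cure_link = link, spline = spline)
  structure(list(spec = spec, par = par,
                 vcov = diag(1e-4, length(par)), vcov_ok = TRUE,
                 loglik = 0, k = length(par), n = 1, n_event = 1,
                 convergence = list(code = 0, restarts = 0, converged = TRUE),
                 design = list(latency_map = list(), incidence_map = list(),
                               latency_cols = character(0),
                               incidence_cols = character(0)),
                 schema = list()),
            class = "cure_model_fit")
}

test_that("mixture fit recovers Weibull truth when no one is cured", {
  cfg <- generator_config(
    n_subjects = 20000,
    cure = list(link = "cloglog", intercept = 10),   # pi ~ 0
    latency = list(shape = 1.4, scale = 3),
    censoring = list(kind = "administrative"),
    study_window_years = 50)                         # complete follow-up
  co <- generate_cohort(cfg, seed = 13)
  expect_equal(mean(co$event), 1)
  fit <- fit_cure_model(cure_model_spec("mixture"), co)
  expect_true(fit$convergence$converged)
  pi_hat <- cure_fraction(fit)$estimate
  expect_lt(pi_hat, 0.02)
  shape_hat <- exp(unname(fit$par["log_shape"]))
  scale_hat <- exp(unname(fit$par["log_scale"]))
  expect_lt(abs(shape_hat - 1.4), 0.05)
  expect_lt(abs(scale_hat - 3), 0.1)
  # independent oracle: a plain Weibull fit on the same complete data
  sr <- survival::survreg(survival::Surv(time_years, event) ~ 1, data = co,
                          dist = "weibull")
  expect_lt(abs(shape_hat - 1 / sr$scale), 0.02)
  expect_lt(abs(scale_hat - exp(unname(coef(sr)[1]))), 0.05)
})

test_that("refitting from the optimum is a fixed point", {
  co <- default_cohort(n = 1200, seed = 5)
  fit <- fit_cure_model(cure_model_spec("nonmixture"), co)
  fit2 <- fit_cure_model(cure_model_spec("nonmixture"), co, init = fit$par)
  expect_equal(fit2$par, fit$par, tolerance = 1e-5)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("covariance is symmetric positive semi-definite at the optimum", {
  co <- default_cohort(n = 1500, seed = 9)
  for (fam in c("mixture", "nonmixture", "flexible")) {
    fit <- fit_cure_model(cure_model_spec(fam), co)
    expect_true(fit$convergence$converged)
    expect_true(fit$vcov_ok)
    expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-6)
    expect_true(min(eigen(fit$vcov, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-10)
    expect_equal(fit$k, 3)
    cf <- cure_fraction(fit)
    expect_true(cf$estimate > 0 && cf$estimate < 1)
    expect_true(cf$lower <= cf$estimate && cf$estimate <= cf$upper)
  }
  expect_error(fit_cure_model(cure_model_spec("mixture"),
                              toy_cohort(c(1, 2), c(0, 0))), "zero events")
})

test_that("population survival behaves across all families", {
  # mixture with pi = 0.5 and unit-exponential latency at t = 1
  fm <- manual_fit("mixture", c(cure_intercept = log(-log(0.5)),
                                log_shape = 0, log_scale = 0))
  expect_equal(predict_survival(fm, 1), 0.5 + 0.5 * exp(-1))  # 0.68394
  expect_equal(predict_survival(fm, 0), 1)
  fn <- manual_fit("nonmixture", c(cure_intercept = log(-log(0.5)),
                                   log_shape = 0, log_scale = 0))
  expect_equal(predict_survival(fn, 1), exp(log(0.5) * (1 - exp(-1))))
  sp <- spline_basis_spec(c(-1, 0, 0.5, 1), cure_constraint = TRUE)
  ff <- manual_fit("flexible", c(gamma0 = -0.3, gamma1 = 0.4,
                                 gamma2 = 0.2), spline = sp)
  grid <- seq(0.05, 20, length.out = 60)
  for (f in list(fm, fn, ff)) {
    s <- predict_survival(f, grid)
    expect_true(all(diff(s) <= 1e-10))
    expect_true(all(s >= 0 & s <= 1))
  }
  # beyond the last knot the flexible survival is exactly flat at the
  # plateau, and equals the model's cure fraction
  s_tail <- predict_survival(ff, c(exp(1), exp(1) + 7, 300))
  expect_equal(s_tail[1], s_tail[2])
  expect_equal(s_tail[2], s_tail[3])
  expect_equal(s_tail[1], cure_fraction(ff)$estimate)
  # large-t limits for the Weibull families approach their cure fraction
  expect_equal(predict_survival(fm, 1e6), 0.5, tolerance = 1e-8)
  expect_equal(predict_survival(fn, 1e6), 0.5, tolerance = 1e-8)
  expect_error(predict_survival(fm, -1), "non-negative")
})

test_that("effect tables are exact transforms of the coefficients", {
  cfg <- paper_default_config(n_subjects = 2500)
  cfg$latency$coef <- c("sex:male" = 0.3)
  cfg$cure$coef <- c("sex:male" = 0.3)
  co <- generate_cohort(cfg, seed = 4)
  fit <- fit_cure_model(
    cure_model_spec("flexible", latency_covariates = c("sex", "age")), co)
  tab <- effect_table(fit)
  nonref <- tab[!tab$reference, ]
  expect_equal(log(nonref$hr), nonref$coefficient, tolerance = 1e-12)
  expect_equal(nonref$cure_ratio, exp(-exp(nonref$coefficient)),
               tolerance = 1e-12)
  expect_equal(nonref$hr_lower,
               exp(nonref$coefficient - qnorm(0.975) * nonref$se))
  expect_true(all(nonref$hr_lower <= nonref$hr &
                    nonref$hr <= nonref$hr_upper))
  ref <- tab[tab$reference, ]
  expect_equal(ref$coefficient, 0)
  expect_equal(ref$hr, 1)
  expect_equal(ref$hr_lower, 1)
  expect_equal(ref$hr_upper, 1)
  expect_equal(ref$level, "female")
})

test_that("cure fraction confidence intervals respect the link scale", {
  co <- default_cohort(n = 2000, seed = 12)
  fit <- fit_cure_model(cure_model_spec("flexible"), co)
  cf <- cure_fraction(fit)
  expect_true(cf$ci_available)
  expect_true(cf$lower > 0 && cf$upper < 1)
  expect_true(cf$lower < cf$estimate && cf$estimate < cf$upper)
  # transform identity: estimate = exp(-exp(eta))
  expect_equal(cf$estimate, exp(-exp(cf$eta)))
})

test_that("rank-deficient designs are refused", {
  co <- default_cohort(n = 300, seed = 2)
  co$dup <- co$age
  attr(co, "schema")$dup <- list(kind = "continuous")
  expect_error(
    fit_cure_model(cure_model_spec("mixture",
                                   latency_covariates = c("age", "dup")),
                   co),
    "rank deficient")
})
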