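test_that("information criteria follow the exact formulas", {
  fake <- list(loglik = -10, k = 3, n = 100)
  ic <- information_criteria(fake)
  expect_equal(unname(ic["AIC"]), 26)
  expect_equal(unname(ic["BIC"]), 20 + 3 * log(100))
  # identity BIC - AIC = k (log n - 2), cross-checked against the printed
  # registry pair (df 3, n 4144): 6695.24 - 6676.25
  expect_equal(3 * (log(4144) - 2), 18.99, tolerance = 1e-3)
  fake2 <- list(loglik = -3338.125, k = 3, n = 4144)
  ic2 <- information_criteria(fake2)
  expect_equal(unname(ic2["BIC"] - ic2["AIC"]), 3 * (log(4144) - 2))
})

test_that("model comparison sorts by AIC and is order-invariant", {
  co <- default_cohort(n = 900, seed = 3)
  fits <- list(
    mixture = fit_cure_model(cure_model_spec("mixture"), co),
    nonmixture = fit_cure_model(cure_model_spec("nonmixture"), co),
    flexible = fit_cure_model(cure_model_spec("flexible"), co))
  tab <- compare_models(fits)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$df, rep(3, 3))
  expect_false(is.unsorted(tab$AIC))
  expect_equal(tab$BIC - tab$AIC, rep(3 * (log(900) - 2), 3))
  tab2 <- compare_models(fits[c(3, 1, 2)])
  expect_equal(tab2$model, tab$model)
  single <- compare_models(fits[1])
  expect_equal(single$rank, 1)
  # refusal on differing cohort sizes
  co2 <- default_cohort(n = 400, seed = 4)
  other <- fit_cure_model(cure_model_spec("mixture"), co2)
  expect_error(compare_models(list(fits[[1]], other)), "differing")
})

test_that("univariate screening assembles one block per candidate", {
  cfg <- paper_default_config(n_subjects = 1500)
  co <- apply_categorization(generate_cohort(cfg, seed = 6))
  tab <- univariate_screen(co, c("sex", "age_cat"), family = "mixture")
  expect_setequal(unique(tab$candidate), c("sex", "age_cat"))
  expect_equal(sum(tab$candidate == "age_cat"), 3)   # ref + 2 levels
  expect_true(all(tab$converged))
  expect_true(all(!is.na(tab$block_p)))
  co$mono <- factor(rep("only", nrow(co)))
  attr(co, "schema")$mono <- list(kind = "categorical", levels = "only",
                                  reference = "only")
  expect_error(univariate_screen(co, "mono"), "single")
})

test_that("screening recovers a known latency log hazard ratio", {
  cfg <- paper_default_config(n_subjects = 4144)
  cfg$latency$coef <- c("sex:male" = 0.4)
  ests <- vapply(1:6, function(s) {
    co <- generate_cohort(cfg, seed = s + 60)
    fit <- fit_cure_model(
      cure_model_spec("mixture", latency_covariates = "sex"), co)
    unname(fit$par["sex:male"])
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.4), 0.05)
})

test_that("null covariates produce approximately uniform p-values", {
  cfg <- paper_default_config(n_subjects = 700)
  ps <- vapply(1:40, function(s) {
    co <- generate_cohort(cfg, seed = s + 500)
    fit <- fit_cure_model(
      cure_model_spec("flexible", latency_covariates = "sex"), co)
    effect_table(fit)$p_value[2]
  }, numeric(1))
  # rejection rate near the nominal 5% level
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps < 0.5), 0.25)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("backward elimination retains a strong effect, drops nulls", {
  cfg <- paper_default_config(n_subjects = 2000)
  cfg$latency$coef <- c("sex:male" = 0.5)
  cfg$cure$coef <- c("sex:male" = 0.5)
  kept <- vapply(1:6, function(s) {
    co <- generate_cohort(cfg, seed = s + 30)
    sel <- backward_eliminate(co, c("sex", "calcium", "ldl"),
                              remove_above = 0.1)
    "sex" %in% sel$final_variables
  }, logical(1))
  expect_gte(sum(kept), 5)
})

test_that("vacuous thresholds remove nothing and traces replay", {
  co <- apply_categorization(default_cohort(n = 1200, seed = 15))
  sel_full <- backward_eliminate(co, c("sex", "age_cat"),
                                 remove_above = 1.0)
  expect_equal(nrow(sel_full$trace), 0)
  expect_setequal(sel_full$final_variables, c("sex", "age_cat"))
  sel <- backward_eliminate(co, c("sex", "age_cat"), remove_above = 0.1)
  # replaying the recorded final variable set reproduces the final fit
  refit <- fit_cure_model(
    cure_model_spec("flexible",
                    latency_covariates = sel$final_variables), co)
  expect_equal(refit$loglik, sel$fit$loglik, tolerance = 1e-8)
  if (nrow(sel$trace) > 0) {
    expect_true(all(sel$trace$p_value >= 0.1))
  }
})

test_that("the full pipeline is deterministic given its seed", {
  cfg <- paper_default_config(n_subjects = 900)
  co <- apply_categorization(generate_cohort(cfg, seed = 44))
  r1 <- run_full_analysis(co, candidates = c("sex", "age_cat"),
                          mz_reps = 120, seed = 7)
  r2 <- run_full_analysis(co, candidates = c("sex", "age_cat"),
                          mz_reps = 120, seed = 7)
  expect_equal(r1$comparison$AIC, r2$comparison$AIC)
  expect_equal(r1$final_effects$coefficient, r2$final_effects$coefficient)
  expect_equal(r1$mz_presence$critical_value, r2$mz_presence$critical_value)
  expect_equal(r1$final_cure_fraction$estimate,
               r2$final_cure_fraction$estimate)
  expect_s3_class(r1$comparison, "model_comparison")
  expect_equal(r1$comparison$df, rep(3, 3))
})
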