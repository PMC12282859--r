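# pdcure

Cure-fraction survival analysis for right-censored registry cohorts in
which a subset of subjects never experiences the event — the situation of
technique survival on peritoneal dialysis (PD), where a plateau in the
Kaplan-Meier curve signals long-term event-free ("cured") patients and
standard Cox or parametric models misattribute that heterogeneity.

The package provides, as one tested pipeline:

- **Nonparametric description** — product-limit estimation with Greenwood
  variance and log(-log) confidence bands, median and fixed-time survival,
  event/censoring tabulations (`km_estimate`, `survival_at`,
  `median_survival`, `cohort_summary`).
- **Maller-Zhou diagnostics** — the test for the *presence* of a cured
  fraction based on the KM CDF at the largest observed time, and the
  five-step *sufficient-follow-up* statistic `q_n = N_n / n`, with bundled
  published critical values and a seeded null simulator
  (`mz_cure_presence_test`, `mz_followup_test`, `mz_critical_value`,
  `simulate_mz_null`).
- **Three cure-model families**, fitted by maximum likelihood
  (`fit_cure_model`):
  - mixture: `S(t) = pi + (1 - pi) S_u(t)` with Weibull latency `S_u`;
  - non-mixture (promotion-time): `S(t) = exp(log(pi) F_u(t))`;
  - flexible parametric: restricted cubic splines for the log cumulative
    hazard on log time, `log H(t|x) = s(log t) + x'beta`, with a
    structural zero-slope constraint beyond the last knot so the fitted
    survival has an exact plateau `pi(x) = exp(-exp(s(k_max) + x'beta))`.
- **Inference** — profile cure fractions with link-scale Wald intervals
  (`cure_fraction`), hazard-ratio effect tables with the
  `exp(-exp(beta))` per-coefficient cure-ratio transform (`effect_table`,
  `hazard_ratio`, `cure_ratio`), population survival curves
  (`predict_survival`).
- **Model building** — AIC/BIC comparison at equal parameter counts,
  univariate screening, backward elimination with block Wald tests, and a
  one-call pipeline (`compare_models`, `univariate_screen`,
  `backward_eliminate`, `run_full_analysis`, `write_report`).
- **A calibrated cohort simulator** (`generator_config`,
  `generate_cohort`, `calibrate_generator`, `paper_default_config`) that
  emulates a national PD registry cohort — n = 4144, 71.66% censored,
  KM median 9.98 years, survival plateau near 0.49 — so the whole pipeline
  is testable without access to any registry export.

## Worked example

```r
library(pdcure)

cfg    <- paper_default_config()          # registry-emulating profile
cohort <- generate_cohort(cfg, seed = 2018)
cohort
#> <cohort> 4144 subjects, 1201 events (28.98%), 7 covariates

km <- km_estimate(cohort)
median_survival(km)
#> [1] 10.10075
survival_at(km, c(3, 5, 10))$estimate
#> [1] 0.7615473 0.6214988 0.5009379
```

About 29% of subjects experience technique failure; survival falls through
76%, 62% and 50% at 3, 5 and 10 years and then flattens. Is the plateau a
cured fraction or an artifact of short follow-up?

```r
mz_cure_presence_test(cohort, "exponential", reps = 300, seed = 1)
#> Maller-Zhou test for a cured fraction
#>   p_hat = 0.5174  (n = 4144, exponential censoring, alpha = 0.05, simulate)
#>   critical value = 0.9692; reject H0: evidence of a cured fraction

mz_followup_test(cohort, censor_model = "exponential", seed = 1)
#> Maller-Zhou sufficient-follow-up test
#>   t_event_max = 11.56, t_obs_max = 18, delta_n = 6.44
#>   window (5.12, 11.56], N_n = 165, q_n = 0.03982
#>   critical value = 0; follow-up sufficient
```

The estimated susceptible proportion (0.52) is far below what a fully
susceptible cohort would show, and events are still plentiful in the
window just below the last failure time: a cured fraction exists and
follow-up suffices to estimate it. Fit the three families and compare:

```r
fits <- list(mixture    = fit_cure_model(cure_model_spec("mixture"), cohort),
             nonmixture = fit_cure_model(cure_model_spec("nonmixture"), cohort),
             flexible   = fit_cure_model(cure_model_spec("flexible"), cohort))
compare_models(fits)
#>        model df    loglik      AIC      BIC rank
#> 1 nonmixture  3 -4159.337 8324.675 8343.663    1
#> 2    mixture  3 -4161.748 8329.495 8348.484    2
#> 3   flexible  3 -4209.093 8424.186 8443.174    3

cf <- cure_fraction(fits$flexible)
sprintf("cure fraction: %.2f (95%% CI %.2f-%.2f)", cf$estimate, cf$lower, cf$upper)
#> [1] "cure fraction: 0.50 (95% CI 0.48-0.52)"
```

All families are compared at the same complexity (df = 3; note the exact
identity `BIC - AIC = k (log n - 2)`). The flexible model's plateau puts
the cure fraction at 0.50 with a ±0.02 interval — recovering the
generator's latent truth of 0.49. Covariate effects, screening and
backward elimination follow the same pattern via
`effect_table(fit)`, `univariate_screen(cohort, candidates)` and
`backward_eliminate(cohort, candidates)`; `run_full_analysis(cohort)`
chains every stage under one seed and `write_report()` serializes the
result.

See the vignette (`vignettes/cure-fraction-methods.Rmd`) for the model
formulations, the constrained-spline construction, the generator's
calibration, and the package's numerical conventions.

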