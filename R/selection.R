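#' Information criteria of a fitted cure model
#'
#' AIC = -2 loglik + 2k and BIC = -2 loglik + k log(n), with k the number
#' of free parameters and n the cohort size; consequently
#' BIC - AIC = k (log n - 2) exactly.
#'
#' @param fit a [fit_cure_model()] result (or any object with `loglik`,
#'   `k`, `n`).
#' @return Named numeric vector `c(AIC =, BIC =)`.
#' @export
information_criteria <- function(fit) {
  c(AIC = -2 * fit$loglik + 2 * fit$k,
    BIC = -2 * fit$loglik + fit$k * log(fit$n))
}

#' Compare fitted cure models by information criteria
#'
#' @param fits list of [fit_cure_model()] results on the same cohort.
#' @param labels optional model labels (defaults to family names).
#' @return Data frame of class `model_comparison` with one row per model
#'   (`model`, `df`, `loglik`, `AIC`, `BIC`), sorted ascending by AIC with
#'   ties broken by BIC then label.
#' @export
compare_models <- function(fits, labels = NULL) {
  stopifnot(length(fits) >= 1L)
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L) {
    stop("fits were made on cohorts of differing size; refusing to compare")
  }
  if (is.null(labels)) {
    labels <- vapply(fits, function(f) f$spec$family, character(1))
    labels <- make.unique(labels)
  }
  ic <- t(vapply(fits, information_criteria, numeric(2)))
  out <- data.frame(model = labels,
                    df = vapply(fits, `[[`, numeric(1), "k"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    AIC = ic[, "AIC"], BIC = ic[, "BIC"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$AIC, out$BIC, out$model), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

# Joint Wald chi-square p-value for all coefficients of one covariate
# (categorical covariates are tested as a whole dummy block).
.wald_block_p <- function(fit, covariate) {
  cols <- fit$design$latency_map[[covariate]]
  if (is.null(cols)) stop("covariate not in the fitted model: ", covariate)
  if (!isTRUE(fit$vcov_ok)) return(NA_real_)
  b <- fit$par[cols]
  V <- fit$vcov[cols, cols, drop = FALSE]
  W <- tryCatch(drop(t(b) %*% solve(V) %*% b), error = function(e) NA_real_)
  stats::pchisq(W, df = length(cols), lower.tail = FALSE)
}

#' Univariate screening of candidate covariates
#'
#' Fits one single-covariate cure model per candidate and assembles the
#' coefficient / HR / confidence-interval rows, together with the block
#' Wald p-value for the candidate as a whole. Non-convergent fits are
#' reported as such, never dropped silently.
#'
#' @param cohort a [as_cohort()] object.
#' @param candidates covariate names to screen.
#' @param family model family (default `"flexible"`).
#' @param ... passed to [fit_cure_model()].
#' @return Data frame with one row per coefficient plus `candidate`,
#'   `block_p` and `converged` columns.
#' @export
univariate_screen <- function(cohort, candidates, family = "flexible", ...) {
  schema <- attr(cohort, "schema")
  for (nm in candidates) {
    if (!nm %in% names(schema)) stop("unknown candidate: ", nm)
    sp <- schema[[nm]]
    if (sp$kind == "categorical" &&
        length(unique(as.character(cohort[[nm]]))) < 2L) {
      stop("candidate has a single observed level: ", nm)
    }
  }
  rows <- lapply(candidates, function(nm) {
    fit <- tryCatch(
      fit_cure_model(cure_model_spec(family, latency_covariates = nm),
                     cohort, ...),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(candidate = nm, covariate = nm, level = "",
                        reference = FALSE, coefficient = NA_real_,
                        se = NA_real_, z = NA_real_, p_value = NA_real_,
                        hr = NA_real_, hr_lower = NA_real_,
                        hr_upper = NA_real_, cure_ratio = NA_real_,
                        block_p = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    tab <- effect_table(fit)
    tab$candidate <- nm
    tab$block_p <- .wald_block_p(fit, nm)
    tab$converged <- fit$convergence$converged
    tab
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("candidate", setdiff(names(out), "candidate"))]
}

#' Backward elimination of covariates in a cure model
#'
#' Starts from the model holding all candidates and iteratively removes the
#' single covariate with the largest block Wald p-value at or above
#' `remove_above`, refitting after each removal, until every remaining
#' covariate is below the threshold. Categorical covariates enter and
#' leave as whole dummy blocks. `final_alpha` flags significance in the
#' final table; it does not drive removal.
#'
#' @param cohort a [as_cohort()] object.
#' @param candidates covariate names for the full model.
#' @param remove_above removal threshold on the block p-value (default 0.1).
#' @param final_alpha significance level for the final model report.
#' @param family model family (default `"flexible"`).
#' @param ... passed to [fit_cure_model()].
#' @return List of class `selection_result`: `fit` (final model), `trace`
#'   (one row per removal: variable, p-value at removal, log-likelihood
#'   before/after), `final_variables`, `thresholds`.
#' @export
backward_eliminate <- function(cohort, candidates, remove_above = 0.1,
                               final_alpha = 0.05, family = "flexible",
                               ...) {
  stopifnot(length(candidates) >= 1L)
  current <- candidates
  fit <- fit_cure_model(
    cure_model_spec(family, latency_covariates = current), cohort, ...)
  if (!fit$convergence$converged) {
    stop("full model did not converge; elimination aborted")
  }
  trace <- data.frame(step = integer(0), removed = character(0),
                      p_value = numeric(0), loglik_before = numeric(0),
                      loglik_after = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(current) == 0L) break
    ps <- vapply(current, function(nm) .wald_block_p(fit, nm), numeric(1))
    worst <- which.max(ps)
    if (!length(worst) || is.na(ps[worst]) || ps[worst] < remove_above) break
    step <- step + 1L
    removed <- current[worst]
    ll_before <- fit$loglik
    current <- setdiff(current, removed)
    fit <- fit_cure_model(
      cure_model_spec(family, latency_covariates = current), cohort, ...)
    trace <- rbind(trace, data.frame(
      step = step, removed = removed, p_value = unname(ps[worst]),
      loglik_before = ll_before, loglik_after = fit$loglik,
      stringsAsFactors = FALSE))
  }
  structure(list(fit = fit, trace = trace, final_variables = current,
                 thresholds = list(remove_above = remove_above,
                                   final_alpha = final_alpha)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Backward elimination (remove at p >= %g):\n",
              x$thresholds$remove_above))
  if (nrow(x$trace) == 0L) {
    cat("  no variable removed\n")
  } else {
    print(x$trace, row.names = FALSE)
  }
  cat("final variables:",
      if (length(x$final_variables)) paste(x$final_variables, collapse = ", ")
      else "(none; null model)", "\n")
  invisible(x)
}

#' Run the full cure-fraction analysis pipeline
#'
#' Executes, in order: cohort summary; Kaplan-Meier estimation with median
#' and fixed-time survival; the Maller-Zhou presence and follow-up tests;
#' covariate-free fits of the three cure-model families with an
#' information-criterion comparison; univariate screening; backward
#' elimination; and the final effect table with the model's cure fraction.
#' Every stochastic stage is driven by the single `seed`.
#'
#' @param cohort a [as_cohort()] object.
#' @param candidates covariates to screen and select over (default: all
#'   schema covariates).
#' @param fixed_times years at which to report survival (default 3, 5, 10).
#' @param censor_model censoring model assumed by the Maller-Zhou tests.
#' @param alpha significance level for the diagnostics.
#' @param remove_above,final_alpha selection thresholds (defaults 0.1 and
#'   0.05).
#' @param mz_reps null-simulation replicates for the diagnostics.
#' @param seed seed controlling every stochastic stage.
#' @return A list of class `pdcure_report` with one element per stage.
#' @export
run_full_analysis <- function(cohort, candidates = NULL,
                              fixed_times = c(3, 5, 10),
                              censor_model = "exponential", alpha = 0.05,
                              remove_above = 0.1, final_alpha = 0.05,
                              mz_reps = 200L, seed = 1L) {
  validate_cohort(cohort)
  if (is.null(candidates)) candidates <- names(attr(cohort, "schema"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  summary_ <- stage("cohort_summary", cohort_summary(cohort))
  km <- stage("km_estimate", km_estimate(cohort))
  med <- median_survival(km)
  surv_fixed <- survival_at(km, fixed_times)
  mz_presence <- stage("mz_presence",
    mz_cure_presence_test(cohort, censor_model, alpha,
                          reps = mz_reps, seed = seed))
  mz_followup <- stage("mz_followup",
    mz_followup_test(cohort, censor_model = censor_model, alpha = alpha,
                     reps = mz_reps, seed = seed))
  null_fits <- stage("null_models", list(
    mixture = fit_cure_model(cure_model_spec("mixture"), cohort,
                             seed = seed),
    nonmixture = fit_cure_model(cure_model_spec("nonmixture"), cohort,
                                seed = seed),
    flexible = fit_cure_model(cure_model_spec("flexible"), cohort,
                              seed = seed)))
  comparison <- stage("compare_models", compare_models(null_fits))
  screen <- stage("univariate_screen",
    univariate_screen(cohort, candidates, seed = seed))
  selection <- stage("backward_eliminate",
    backward_eliminate(cohort, candidates, remove_above = remove_above,
                       final_alpha = final_alpha, seed = seed))
  final_effects <- stage("effect_table", effect_table(selection$fit))
  final_cure <- stage("cure_fraction", cure_fraction(selection$fit))
  structure(list(
    seed = seed,
    n = nrow(cohort),
    cohort_summary = summary_,
    km = km, median_survival = med, survival_at = surv_fixed,
    mz_presence = mz_presence, mz_followup = mz_followup,
    null_fits = null_fits, comparison = comparison,
    univariate = screen, selection = selection,
    final_effects = final_effects, final_cure_fraction = final_cure,
    thresholds = list(remove_above = remove_above,
                      final_alpha = final_alpha)
  ), class = "pdcure_report")
}
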