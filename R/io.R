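#' Read a cohort from delimited text
#'
#' Parses the package's cohort exchange format: comma-delimited text with a
#' header row and columns `id`, `time_years`, `event`, then covariates.
#' Rows with any missing value are excluded (complete-case) and counted;
#' the count is attached as attribute `n_excluded` and reported via a
#' message.
#'
#' @param path file path.
#' @param schema optional covariate schema (see [cohort_schema()]);
#'   inferred from column types when omitted.
#' @return A [as_cohort()] object.
#' @export
read_cohort <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty cohort file: ", path)
  for (col in c("id", "time_years", "event")) {
    if (!col %in% names(raw)) stop("missing required column: ", col)
  }
  if (!is.numeric(raw$time_years)) {
    stop("non-numeric follow-up time in column 'time_years'")
  }
  if (!all(raw$event %in% c(0, 1, NA))) {
    stop("event column must contain only 0 (censored) and 1 (event)")
  }
  keep <- stats::complete.cases(raw)
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message("excluded ", n_excluded, " incomplete record",
            if (n_excluded > 1L) "s", " (complete-case analysis)")
  }
  cohort <- as_cohort(raw[keep, , drop = FALSE], schema = schema)
  cohort <- validate_cohort(cohort)
  attr(cohort, "n_excluded") <- n_excluded
  cohort
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]. Latent validation columns are dropped;
#' missing values are not permitted on write.
#'
#' @param cohort a [as_cohort()] object.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out <- out[, setdiff(names(out), c(".cured", ".latent_time")),
             drop = FALSE]
  if (anyNA(out)) stop("cohort contains missing values; refusing to write")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Formatting helpers matching the precision used in registry reports:
# coefficients and hazard ratios to 3 decimals, cure ratios to 2,
# information criteria to 2.
.fmt <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
}

.fmt_effects <- function(tab) {
  data.frame(
    covariate = tab$covariate, level = tab$level,
    coefficient = .fmt(tab$coefficient, 3),
    se = .fmt(tab$se, 3),
    p_value = ifelse(is.na(tab$p_value), "",
                     ifelse(tab$p_value < 0.001, "<0.001",
                            .fmt(tab$p_value, 3))),
    HR = .fmt(tab$hr, 3),
    HR_lower = .fmt(tab$hr_lower, 3),
    HR_upper = .fmt(tab$hr_upper, 3),
    cure_ratio = .fmt(tab$cure_ratio, 2),
    stringsAsFactors = FALSE)
}

# Plain-numbers view of a report for serialization.
.report_payload <- function(report) {
  ic <- report$comparison
  list(
    seed = report$seed,
    n = report$n,
    events = list(n_event = report$cohort_summary$n_event,
                  n_censored = report$cohort_summary$n_censored,
                  pct_event = report$cohort_summary$pct_event,
                  pct_censored = report$cohort_summary$pct_censored),
    km = list(median_survival_years = report$median_survival,
              survival_at = report$survival_at),
    mz = list(p_hat = report$mz_presence$p_hat,
              p_hat_critical = report$mz_presence$critical_value,
              reject_no_cure = report$mz_presence$reject_h0,
              q_n = report$mz_followup$q_n,
              N_n = report$mz_followup$N_n,
              window = report$mz_followup$window,
              q_n_critical = report$mz_followup$critical_value,
              followup_sufficient = report$mz_followup$sufficient),
    model_comparison = as.data.frame(ic),
    final_variables = report$selection$final_variables,
    elimination_trace = report$selection$trace,
    final_effects = as.data.frame(report$final_effects),
    cure_fraction = report$final_cure_fraction[
      c("estimate", "lower", "upper")],
    thresholds = report$thresholds
  )
}

#' Write an analysis report to disk
#'
#' Serializes a [run_full_analysis()] report with deterministic field
#' ordering. `"text"` writes a human-readable summary whose numeric
#' formatting follows registry-report precision (coefficients and HRs to 3
#' decimals, cure ratios to 2, AIC/BIC to 2); `"json"` writes the full
#' payload; `"csv"` writes the tabular components (`<stem>_comparison.csv`,
#' `<stem>_univariate.csv`, `<stem>_effects.csv`, `<stem>_km.csv`).
#'
#' @param report a `pdcure_report`.
#' @param path output file path (for `"csv"`, the stem).
#' @param format `"text"`, `"json"` or `"csv"`.
#' @return The path(s) written, invisibly.
#' @export
write_report <- function(report, path, format = c("text", "json", "csv")) {
  stopifnot(inherits(report, "pdcure_report"))
  format <- match.arg(format)
  payload <- .report_payload(report)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  if (format == "csv") {
    stem <- sub("\\.csv$", "", path)
    paths <- c(comparison = paste0(stem, "_comparison.csv"),
               univariate = paste0(stem, "_univariate.csv"),
               effects = paste0(stem, "_effects.csv"),
               km = paste0(stem, "_km.csv"))
    utils::write.csv(as.data.frame(report$comparison), paths["comparison"],
                     row.names = FALSE)
    utils::write.csv(report$univariate, paths["univariate"],
                     row.names = FALSE)
    utils::write.csv(.fmt_effects(report$final_effects), paths["effects"],
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$km), paths["km"],
                     row.names = FALSE)
    return(invisible(paths))
  }
  ic <- report$comparison
  lines <- c(
    "pdcure analysis report",
    sprintf("seed: %d", report$seed),
    sprintf("subjects: %d (%d events %s%%, %d censored %s%%)",
            report$n, report$cohort_summary$n_event,
            .fmt(report$cohort_summary$pct_event, 2),
            report$cohort_summary$n_censored,
            .fmt(report$cohort_summary$pct_censored, 2)),
    sprintf("KM median survival: %s years",
            .fmt(report$median_survival, 2)),
    paste0("survival at ",
           paste(sprintf("%g y: %s", report$survival_at$time,
                         .fmt(report$survival_at$estimate, 2)),
                 collapse = ", ")),
    sprintf("Maller-Zhou p_hat = %s (critical %s) -> %s",
            .fmt(report$mz_presence$p_hat, 3),
            .fmt(report$mz_presence$critical_value, 3),
            if (isTRUE(report$mz_presence$reject_h0))
              "cured fraction present" else "no cured fraction demonstrated"),
    sprintf("Maller-Zhou q_n = %s (critical %s) -> follow-up %s",
            .fmt(report$mz_followup$q_n, 3),
            .fmt(report$mz_followup$critical_value, 3),
            if (isTRUE(report$mz_followup$sufficient)) "sufficient"
            else "not demonstrated sufficient"),
    "",
    "model comparison (no covariates):",
    sprintf("  %-12s df %d  loglik %s  AIC %s  BIC %s",
            ic$model, ic$df, .fmt(ic$loglik, 2), .fmt(ic$AIC, 2),
            .fmt(ic$BIC, 2)),
    "",
    sprintf("selection thresholds: remove at p >= %g, final alpha %g",
            report$thresholds$remove_above, report$thresholds$final_alpha),
    sprintf("final variables: %s",
            if (length(report$selection$final_variables))
              paste(report$selection$final_variables, collapse = ", ")
            else "(none)"),
    "",
    "final model effects:",
    utils::capture.output(print(.fmt_effects(report$final_effects),
                                row.names = FALSE)),
    "",
    sprintf("cure fraction: %s (%s, %s)",
            .fmt(report$final_cure_fraction$estimate, 2),
            .fmt(report$final_cure_fraction$lower, 2),
            .fmt(report$final_cure_fraction$upper, 2))
  )
  writeLines(lines, path)
  invisible(path)
}
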