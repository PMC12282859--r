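#' Subject-level right-censored cohort
#'
#' A `cohort` is a data frame with one row per subject and the mandatory
#' columns `id`, `time_years` (follow-up in years, strictly positive) and
#' `event` (1 = event observed, 0 = right-censored), plus any number of
#' covariate columns described by a schema. The schema records, for every
#' covariate, whether it is continuous or categorical and, for categorical
#' covariates, the ordered level set with a declared reference level.
#'
#' Synthetically generated cohorts may additionally carry the latent columns
#' `.cured` (true long-term survivor status) and `.latent_time` (uncensored
#' event time, `Inf` for cured subjects). These are retained for validation
#' only and are never written to disk.
#'
#' @param data data frame holding `id`, `time_years`, `event` and covariates.
#' @param covariates character vector naming the covariate columns; defaults
#'   to every column other than the mandatory three and the latent columns.
#' @param schema optional pre-built schema (as returned by
#'   [cohort_schema()]); inferred from column types when omitted.
#' @return An object of class `cohort` (a data frame with a `schema`
#'   attribute).
#' @export
as_cohort <- function(data, covariates = NULL, schema = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  required <- c("id", "time_years", "event")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data),
                          c(required, ".cured", ".latent_time"))
  }
  if (is.null(schema)) schema <- cohort_schema(data, covariates)
  structure(data, schema = schema, class = c("cohort", "data.frame"))
}

#' Build a covariate schema from observed columns
#'
#' Character and factor columns become categorical covariates (reference =
#' first level); numeric columns become continuous covariates.
#'
#' @param data data frame of covariate values.
#' @param covariates names of the covariate columns to describe.
#' @return Named list of covariate descriptors.
#' @export
cohort_schema <- function(data, covariates) {
  schema <- lapply(covariates, function(nm) {
    x <- data[[nm]]
    if (is.numeric(x)) {
      list(kind = "continuous")
    } else {
      lev <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
      list(kind = "categorical", levels = lev, reference = lev[1L])
    }
  })
  names(schema) <- covariates
  schema
}

#' @export
print.cohort <- function(x, ...) {
  sch <- attr(x, "schema")
  cat(sprintf("<cohort> %d subjects, %d events (%.2f%%), %d covariates\n",
              nrow(x), sum(x$event), 100 * mean(x$event), length(sch)))
  if (length(sch) > 0) {
    kinds <- vapply(sch, `[[`, "", "kind")
    cat("  covariates:",
        paste(sprintf("%s (%s)", names(sch), substr(kinds, 1, 4)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Validate the cohort invariants; called by generators and readers.
validate_cohort <- function(cohort) {
  if (!inherits(cohort, "cohort")) stop("not a cohort object")
  t <- cohort$time_years
  d <- cohort$event
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("follow-up times must be strictly positive and finite")
  }
  if (!all(d %in% c(0, 1))) {
    stop("event indicator must be 0 (censored) or 1 (event)")
  }
  sch <- attr(cohort, "schema")
  for (nm in names(sch)) {
    if (!nm %in% names(cohort)) stop("schema covariate absent: ", nm)
    if (anyNA(cohort[[nm]])) {
      stop("missing values in covariate '", nm, "' (complete cases required)")
    }
  }
  if (".cured" %in% names(cohort) && ".latent_time" %in% names(cohort)) {
    cured <- cohort$.cured
    if (any(cured & is.finite(cohort$.latent_time))) {
      stop("latent cure status implies an infinite latent event time")
    }
    if (any(cured & cohort$event == 1)) {
      stop("cured subjects cannot have an observed event")
    }
  }
  invisible(cohort)
}

# Linear predictor for a named coefficient vector against cohort covariates.
# Continuous terms are named after the covariate ("age"); indicator terms for
# a categorical level use "covariate:level" ("sex:male").
linear_predictor <- function(coef, data, schema) {
  if (is.null(coef) || length(coef) == 0L) return(rep(0, nrow(data)))
  if (is.null(names(coef)) || any(names(coef) == "")) {
    stop("coefficients must be named")
  }
  lp <- rep(0, nrow(data))
  for (nm in names(coef)) {
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
      cov <- parts[1L]; lev <- paste(parts[-1L], collapse = ":")
      if (!cov %in% names(schema)) {
        stop("coefficient references unknown covariate: ", cov)
      }
      lp <- lp + coef[[nm]] * as.numeric(as.character(data[[cov]]) == lev)
    } else {
      if (!nm %in% names(schema)) {
        stop("coefficient references unknown covariate: ", nm)
      }
      if (schema[[nm]]$kind != "continuous") {
        stop("coefficient '", nm, "' must name a level as 'covariate:level'")
      }
      lp <- lp + coef[[nm]] * data[[nm]]
    }
  }
  lp
}

#' Categorize continuous covariates by clinical cut-points
#'
#' Adds categorical versions of continuous covariates using named cut-point
#' rules. Each rule gives strictly increasing cut-points, per-cut closure
#' (does a value equal to the cut-point fall in the lower category?) and
#' category labels. The default rules are the clinical bandings used for
#' registry reporting: age 20-40 / 40-60 / >60 (left-closed, so 40 falls in
#' "40-60"), calcium <8.2 / 8.2-10.2 / >10.2 mg/dl and LDL <100 / 100-140 /
#' >140 (middle interval closed on both sides, so 8.2 and 10.2 both fall in
#' "8.2-10.2"). The original continuous columns are retained and the lowest
#' interval becomes the reference level of the new `<name>_cat` column.
#'
#' @param cohort a [as_cohort()] object.
#' @param rules named list of rules, each
#'   `list(cuts =, right_closed =, labels =)`; defaults to
#'   [default_categorization_rules()] restricted to covariates present.
#' @return The cohort with added categorical columns and extended schema.
#' @export
apply_categorization <- function(cohort, rules = NULL) {
  schema <- attr(cohort, "schema")
  if (is.null(rules)) {
    rules <- default_categorization_rules()
    rules <- rules[intersect(names(rules), names(schema))]
  }
  for (nm in names(rules)) {
    if (!nm %in% names(schema)) stop("rule references unknown covariate: ", nm)
    if (schema[[nm]]$kind != "continuous") {
      stop("cannot categorize non-numeric covariate: ", nm)
    }
    r <- rules[[nm]]
    cuts <- r$cuts
    if (is.unsorted(cuts, strictly = TRUE)) {
      stop("cut-points must be strictly increasing for: ", nm)
    }
    right_closed <- if (is.null(r$right_closed)) {
      rep(FALSE, length(cuts))
    } else r$right_closed
    labels <- r$labels
    stopifnot(length(labels) == length(cuts) + 1L,
              length(right_closed) == length(cuts))
    x <- cohort[[nm]]
    idx <- rep(1L, length(x))
    for (j in seq_along(cuts)) {
      above <- if (right_closed[j]) x > cuts[j] else x >= cuts[j]
      idx <- pmax(idx, as.integer(above) * (j + 1L))
    }
    counts <- tabulate(idx, nbins = length(labels))
    if (any(counts == 0L)) {
      warning("empty categor", if (sum(counts == 0) > 1) "ies" else "y",
              " for '", nm, "': ",
              paste(labels[counts == 0L], collapse = ", "))
    }
    new_nm <- paste0(nm, "_cat")
    cohort[[new_nm]] <- factor(labels[idx], levels = labels)
    schema[[new_nm]] <- list(kind = "categorical", levels = labels,
                             reference = labels[1L])
  }
  attr(cohort, "schema") <- schema
  cohort
}

#' @rdname apply_categorization
#' @export
default_categorization_rules <- function() {
  list(
    age = list(cuts = c(40, 60),
               right_closed = c(FALSE, FALSE),
               labels = c("20-40", "40-60", ">60")),
    calcium = list(cuts = c(8.2, 10.2),
                   right_closed = c(FALSE, TRUE),
                   labels = c("<8.2", "8.2-10.2", ">10.2")),
    ldl = list(cuts = c(100, 140),
               right_closed = c(FALSE, TRUE),
               labels = c("<100", "100-140", ">140"))
  )
}

#' Event/censoring summary of a cohort
#'
#' Overall event and censoring counts with percentages (rounded to two
#' decimals), cross-tabulated by every categorical covariate in the schema.
#'
#' @param cohort a [as_cohort()] object.
#' @return A list of class `cohort_summary` with elements `n`, `n_event`,
#'   `n_censored`, `pct_event`, `pct_censored` and `by_covariate`, a named
#'   list of per-category count/percentage tables.
#' @export
cohort_summary <- function(cohort) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  n_event <- sum(cohort$event == 1)
  n_cens <- n - n_event
  schema <- attr(cohort, "schema")
  cats <- names(schema)[vapply(schema, `[[`, "", "kind") == "categorical"]
  by_cov <- lapply(cats, function(nm) {
    lev <- schema[[nm]]$levels
    x <- factor(as.character(cohort[[nm]]), levels = lev)
    tab <- table(x, factor(cohort$event, levels = c(0, 1)))
    row_n <- rowSums(tab)
    data.frame(
      category = lev,
      n_censored = as.integer(tab[, "0"]),
      pct_censored = round(100 * tab[, "0"] / pmax(row_n, 1), 2),
      n_event = as.integer(tab[, "1"]),
      pct_event = round(100 * tab[, "1"] / pmax(row_n, 1), 2),
      row.names = NULL
    )
  })
  names(by_cov) <- cats
  structure(
    list(n = n, n_event = n_event, n_censored = n_cens,
         pct_event = round(100 * n_event / n, 2),
         pct_censored = round(100 * n_cens / n, 2),
         by_covariate = by_cov),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("n = %d: %d events (%.2f%%), %d censored (%.2f%%)\n",
              x$n, x$n_event, x$pct_event, x$n_censored, x$pct_censored))
  for (nm in names(x$by_covariate)) {
    cat("\n", nm, ":\n", sep = "")
    print(x$by_covariate[[nm]], row.names = FALSE)
  }
  invisible(x)
}
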