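#' Product-limit (Kaplan-Meier) survival curve
#'
#' Computes the Kaplan-Meier estimate with Greenwood variance and pointwise
#' 95% confidence bands on the log(-log) scale (which keeps the bands inside
#' \[0,1\]). Ties between events and censorings at the same instant follow
#' the standard risk-set convention: events precede censorings.
#'
#' @param cohort a [as_cohort()] object (or any data frame with
#'   `time_years` and `event`).
#' @param conf_level confidence level for the pointwise bands.
#' @return An object of class `km_curve`: a data frame with one row per
#'   distinct observed time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `var_greenwood`, `lower`, `upper`) plus attributes `n`,
#'   `t_max_obs`, `t_max_event` and `conf_level`.
#' @export
km_estimate <- function(cohort, conf_level = 0.95) {
  if (nrow(cohort) < 1L) stop("empty cohort")
  if (any(cohort$time_years <= 0)) stop("times must be strictly positive")
  fit <- survival::survfit(
    survival::Surv(time_years, event) ~ 1,
    data = cohort, conf.type = "log-log", conf.int = conf_level
  )
  curve <- data.frame(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    var_greenwood = (fit$std.err * fit$surv)^2,
    lower = pmin(pmax(ifelse(is.na(fit$lower) & fit$surv == 0, 0, fit$lower),
                      0), 1),
    upper = pmin(pmax(ifelse(is.na(fit$upper) & fit$surv == 0, 0, fit$upper),
                      0), 1)
  )
  # with no events at all survfit may report NA bands; the curve is flat 1
  curve$var_greenwood[is.na(curve$var_greenwood)] <- 0
  curve$lower[is.na(curve$lower) & curve$surv == 1] <- 1
  curve$upper[is.na(curve$upper)] <- 1
  ev <- curve$time[curve$n_event > 0]
  structure(curve,
            n = nrow(cohort),
            t_max_obs = max(cohort$time_years),
            t_max_event = if (length(ev)) max(ev) else NA_real_,
            conf_level = conf_level,
            class = c("km_curve", "data.frame"))
}

#' Survival probability at given times
#'
#' Right-continuous step-function lookup on a [km_estimate()] curve: the
#' value at `t` is the estimate at the last observed time not exceeding `t`
#' (1 before the first). Times beyond the last observed time return the
#' tail value flagged as extrapolated.
#'
#' @param curve a `km_curve`.
#' @param t non-negative times (years); vectorized.
#' @return Data frame with `time`, `estimate`, `lower`, `upper`,
#'   `extrapolated`.
#' @export
survival_at <- function(curve, t) {
  if (any(t < 0)) stop("t must be non-negative")
  idx <- findInterval(t, curve$time)
  est <- ifelse(idx == 0, 1, curve$surv[pmax(idx, 1L)])
  lo <- ifelse(idx == 0, 1, curve$lower[pmax(idx, 1L)])
  up <- ifelse(idx == 0, 1, curve$upper[pmax(idx, 1L)])
  data.frame(time = t, estimate = est, lower = lo, upper = up,
             extrapolated = t > attr(curve, "t_max_obs"))
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest event time at which the survival estimate drops to 0.5 or
#' below (no interpolation). Returns `NA` when the curve never reaches 0.5,
#' as happens with a large cured fraction.
#'
#' @param curve a `km_curve`.
#' @return Median survival in years, or `NA_real_` when undefined.
#' @export
median_survival <- function(curve) {
  at_event <- curve$n_event > 0
  hit <- at_event & curve$surv <= 0.5
  if (!any(hit)) return(NA_real_)
  min(curve$time[hit])
}
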