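#' Cure-model log-likelihoods
#'
#' Direct evaluation of the three cure-model log-likelihoods on a cohort,
#' on the natural parameter scale. All three return `-Inf` (never an error)
#' for parameter values outside the admissible domain or whenever a
#' non-finite term arises, so they are safe to hand to an optimizer.
#'
#' The mixture model mixes a cured class of size pi with Weibull latency
#' for the susceptible: S_pop(t) = pi + (1 - pi) S_u(t); an event
#' contributes log((1 - pi) f_u(t)) and a censored subject
#' log(pi + (1 - pi) S_u(t)). Covariates act on the latency log hazard
#' (proportional hazards) and, through the chosen link, on the
#' cure probability.
#'
#' The non-mixture (promotion-time) model sets
#' S_pop(t) = exp(log(pi) F_u(t)) = exp(-theta F_u(t)) with
#' theta = -log(pi), so the population hazard is theta f_u(t) and the cure
#' fraction is reached asymptotically. Covariates scale theta
#' (equivalently, act proportionally on the population hazard).
#'
#' The flexible parametric model writes the log cumulative hazard as a
#' spline in log time, log H(t | x) = s(log t) + x'beta with
#' s(u) = gamma_0 + sum_j gamma_j basis_j(u); then S = exp(-H) and an event
#' contributes log s'(log t) - log t + log H(t). With the cure-constrained
#' basis the fitted survival is exactly flat beyond the last knot and the
#' plateau value exp(-exp(s(k_max) + x'beta)) is the cure fraction.
#'
#' @param cohort a [as_cohort()] object (only `time_years`, `event` and the
#'   referenced covariates are used).
#' @param pi cure fraction at covariate reference (in \[0, 1) for the
#'   mixture model, (0, 1) for the non-mixture model).
#' @param shape,scale Weibull latency parameters (> 0);
#'   S_u(t) = exp(-(t / scale)^shape).
#' @param coef_latency named coefficients on the latency log hazard
#'   (mixture) or on log theta (non-mixture); see [linear_predictor()].
#' @param coef_incidence named coefficients on the cure-probability link
#'   scale (mixture only).
#' @param link cure-probability link, `"cloglog"` (pi = exp(-exp(eta))) or
#'   `"logit"`.
#' @return A single log-likelihood value (possibly `-Inf`).
#' @name cure_loglik
NULL

.cloglog <- function(p) log(-log(p))
.inv_cloglog <- function(eta) exp(-exp(eta))

.link_eta <- function(p, link) {
  switch(link, cloglog = .cloglog(p), logit = stats::qlogis(p),
         stop("unknown cure link: ", link))
}
.inv_link <- function(eta, link) {
  switch(link, cloglog = .inv_cloglog(eta), logit = stats::plogis(eta),
         stop("unknown cure link: ", link))
}

#' @rdname cure_loglik
#' @export
loglik_mixture <- function(cohort, pi, shape, scale,
                           coef_latency = NULL, coef_incidence = NULL,
                           link = "cloglog") {
  y <- cohort$time_years; d <- cohort$event
  if (any(y <= 0)) stop("non-positive follow-up time")
  if (!is.finite(shape) || !is.finite(scale) || shape <= 0 || scale <= 0 ||
      !is.finite(pi) || pi < 0 || pi >= 1) {
    return(-Inf)
  }
  schema <- attr(cohort, "schema")
  lp_lat <- linear_predictor(coef_latency, cohort, schema)
  pi_i <- if (is.null(coef_incidence) || length(coef_incidence) == 0L) {
    rep(pi, length(y))
  } else {
    if (pi <= 0) return(-Inf)
    .inv_link(.link_eta(pi, link) +
                linear_predictor(coef_incidence, cohort, schema), link)
  }
  if (any(!is.finite(pi_i)) || any(pi_i < 0) || any(pi_i >= 1)) return(-Inf)
  .ll_mixture_core(y, d, pi_i, shape, scale, lp_lat)
}

.ll_mixture_core <- function(y, d, pi_i, shape, scale, lp_lat) {
  logH <- shape * (log(y) - log(scale)) + lp_lat
  H <- exp(logH)
  logS <- -H
  log_h <- log(shape) - log(y) + logH
  ll_event <- log1p(-pi_i) + log_h + logS
  ll_cens <- log(pi_i + (1 - pi_i) * exp(logS))
  ll <- sum(ifelse(d == 1, ll_event, ll_cens))
  if (!is.finite(ll)) -Inf else ll
}

#' @rdname cure_loglik
#' @export
loglik_nonmixture <- function(cohort, pi, shape, scale,
                              coef_latency = NULL, link = "cloglog") {
  y <- cohort$time_years; d <- cohort$event
  if (any(y <= 0)) stop("non-positive follow-up time")
  if (!is.finite(shape) || !is.finite(scale) || shape <= 0 || scale <= 0 ||
      !is.finite(pi) || pi <= 0 || pi >= 1) {
    return(-Inf)
  }
  schema <- attr(cohort, "schema")
  lp <- linear_predictor(coef_latency, cohort, schema)
  theta_i <- -log(pi) * exp(lp)
  .ll_nonmixture_core(y, d, theta_i, shape, scale)
}

.ll_nonmixture_core <- function(y, d, theta_i, shape, scale) {
  Hu <- (y / scale)^shape
  Fu <- -expm1(-Hu)
  log_fu <- log(shape) - log(y) + shape * (log(y) - log(scale)) - Hu
  ll <- sum(d * (log(theta_i) + log_fu) - theta_i * Fu)
  if (!is.finite(ll)) -Inf else ll
}

#' @rdname cure_loglik
#' @param gamma spline coefficients `c(intercept, one per basis column)`.
#' @param spline a [spline_basis_spec()]; its `cure_constraint` flag picks
#'   the constrained or unconstrained basis.
#' @param coef named covariate coefficients on the log cumulative hazard
#'   (flexible model).
#' @export
loglik_flexible <- function(cohort, gamma, spline, coef = NULL) {
  y <- cohort$time_years; d <- cohort$event
  if (any(y <= 0)) stop("non-positive follow-up time")
  stopifnot(inherits(spline, "spline_basis_spec"))
  if (length(gamma) != spline$n_basis + 1L) {
    stop("gamma must have length n_basis + 1 (intercept first)")
  }
  schema <- attr(cohort, "schema")
  lp <- linear_predictor(coef, cohort, schema)
  u <- log(y)
  bas <- .spline_eval(u, spline)
  .ll_flexible_core(u, d, bas$basis, bas$deriv, gamma, lp)
}

.ll_flexible_core <- function(u, d, basis, deriv, gamma, lp) {
  if (any(!is.finite(gamma)) || any(!is.finite(lp))) return(-Inf)
  s <- gamma[1L] + drop(basis %*% gamma[-1L]) + lp
  sprime <- drop(deriv %*% gamma[-1L])
  ev <- d == 1
  if (any(sprime[ev] <= 0)) return(-Inf)  # hazard must be positive at events
  H <- exp(s)
  ll <- sum(log(sprime[ev]) - u[ev] + s[ev]) - sum(H)
  if (!is.finite(ll)) -Inf else ll
}
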