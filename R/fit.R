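#' Specify a cure model
#'
#' @param family `"mixture"` (Weibull latency mixed with a cured class),
#'   `"nonmixture"` (promotion-time with Weibull kernel) or `"flexible"`
#'   (restricted cubic spline on the log cumulative hazard with an exact
#'   cure plateau).
#' @param latency_covariates covariates on the latency log hazard (mixture),
#'   on log theta (non-mixture) or on the log cumulative hazard (flexible).
#' @param incidence_covariates covariates on the cure-probability link scale
#'   (mixture family only).
#' @param cure_link `"cloglog"` (default; pi = exp(-exp(eta))) or `"logit"`.
#' @param spline a [spline_basis_spec()] for the flexible family; when
#'   `NULL`, knots are placed at fit time: boundary knots at the extreme
#'   uncensored log event times and `n_interior_knots` interior knots at
#'   event-time centiles.
#' @param n_interior_knots interior knots for automatic placement (default
#'   2, giving 2 free spline coefficients + intercept under the cure
#'   constraint: 3 free parameters in the covariate-free model).
#' @param cure_constraint force the spline survival tail flat (default
#'   TRUE; turning it off gives an ordinary log-cumulative-hazard spline
#'   model without a cure interpretation).
#' @return An object of class `cure_model_spec`.
#' @export
cure_model_spec <- function(family = c("flexible", "mixture", "nonmixture"),
                            latency_covariates = character(),
                            incidence_covariates = character(),
                            cure_link = c("cloglog", "logit"),
                            spline = NULL, n_interior_knots = 2L,
                            cure_constraint = TRUE) {
  family <- match.arg(family)
  cure_link <- match.arg(cure_link)
  if (family != "mixture" && length(incidence_covariates) > 0L) {
    stop("incidence covariates are only meaningful for the mixture family")
  }
  structure(list(family = family,
                 latency_covariates = latency_covariates,
                 incidence_covariates = incidence_covariates,
                 cure_link = cure_link, spline = spline,
                 n_interior_knots = n_interior_knots,
                 cure_constraint = cure_constraint),
            class = "cure_model_spec")
}

# Design matrix with reference-coded indicator columns named "cov:level";
# map records which columns belong to each covariate (for block Wald tests).
.build_design <- function(covariates, cohort) {
  schema <- attr(cohort, "schema")
  cols <- list()
  map <- list()
  for (nm in covariates) {
    if (!nm %in% names(schema)) stop("unknown covariate: ", nm)
    sp <- schema[[nm]]
    if (sp$kind == "continuous") {
      cols[[nm]] <- as.numeric(cohort[[nm]])
      map[[nm]] <- nm
    } else {
      nonref <- setdiff(sp$levels, sp$reference)
      if (length(nonref) == 0L) {
        stop("covariate has a single level: ", nm)
      }
      for (lv in nonref) {
        cn <- paste0(nm, ":", lv)
        cols[[cn]] <- as.numeric(as.character(cohort[[nm]]) == lv)
        map[[nm]] <- c(map[[nm]], cn)
      }
    }
  }
  X <- if (length(cols)) {
    do.call(cbind, cols)
  } else {
    matrix(numeric(0), nrow(cohort), 0)
  }
  if (length(cols)) colnames(X) <- names(cols)
  list(X = X, map = map)
}

# Data-driven starting values shared by the three families.
.init_values <- function(y, d) {
  p0 <- min(max(.km_tail(y, d), 0.02), 0.95)
  wb <- tryCatch({
    sr <- survival::survreg(survival::Surv(y, d) ~ 1, dist = "weibull")
    c(shape = 1 / sr$scale, scale = exp(unname(sr$coefficients[1L])))
  }, error = function(e) c(shape = 1, scale = stats::median(y)))
  list(p0 = p0, shape = unname(wb["shape"]), scale = unname(wb["scale"]))
}

#' Fit a cure model by maximum likelihood
#'
#' Maximizes the family log-likelihood by quasi-Newton (BFGS) search on an
#' unconstrained reparametrization (log Weibull shape/scale; cure
#' probability on its link scale). The covariance matrix is the inverse of
#' the numerically differentiated observed information at the optimum. On
#' convergence failure the search restarts from seeded jitters of the
#' data-driven initial values.
#'
#' @param spec a [cure_model_spec()].
#' @param cohort a [as_cohort()] object with at least one event.
#' @param init optional named numeric vector of starting values on the
#'   working scale (advanced use; must match the internal parameter order).
#' @param max_iter,reltol optimizer controls.
#' @param seed seed for the multistart jitters.
#' @param multistart maximum number of restarts on failure.
#' @return An object of class `cure_model_fit` with elements `par`
#'   (working-scale estimates), `vcov`, `loglik`, `k`, `n`, `n_event`,
#'   `convergence`, resolved `spec` and design metadata.
#' @export
fit_cure_model <- function(spec, cohort, init = NULL,
                           max_iter = 1000L, reltol = 1e-10,
                           seed = 1L, multistart = 5L) {
  stopifnot(inherits(spec, "cure_model_spec"))
  validate_cohort(cohort)
  y <- cohort$time_years
  d <- cohort$event
  if (sum(d) == 0L) stop("cannot fit a cure model with zero events")

  lat <- .build_design(spec$latency_covariates, cohort)
  inc <- .build_design(spec$incidence_covariates, cohort)
  p_lat <- ncol(lat$X); p_inc <- ncol(inc$X)
  if (p_lat > 0L &&
      qr(cbind(1, lat$X))$rank < p_lat + 1L) {
    stop("latency design matrix is rank deficient")
  }

  family <- spec$family
  if (family == "flexible" && is.null(spec$spline)) {
    spec$spline <- spline_basis_spec(
      .default_knots(cohort, spec$n_interior_knots),
      cure_constraint = spec$cure_constraint)
  }

  iv <- .init_values(y, d)
  eta0 <- .link_eta(iv$p0, spec$cure_link)

  if (family == "mixture") {
    par0 <- c(cure_intercept = eta0,
              if (p_inc) stats::setNames(rep(0, p_inc),
                                         paste0("cure_", colnames(inc$X))),
              log_shape = log(iv$shape), log_scale = log(iv$scale),
              if (p_lat) stats::setNames(rep(0, p_lat), colnames(lat$X)))
    Xi <- inc$X; Xl <- lat$X; lnk <- spec$cure_link
    negll <- function(par) {
      eta <- par[1L] + if (p_inc) drop(Xi %*% par[2:(1 + p_inc)]) else 0
      pi_i <- .inv_link(eta, lnk)
      shape <- exp(par[p_inc + 2L]); scale <- exp(par[p_inc + 3L])
      lp <- if (p_lat) drop(Xl %*% par[(p_inc + 4L):(p_inc + 3L + p_lat)])
            else rep(0, length(y))
      ll <- .ll_mixture_core(y, d, pi_i, shape, scale, lp)
      if (!is.finite(ll)) 1e10 else -ll
    }
  } else if (family == "nonmixture") {
    par0 <- c(cure_intercept = .cloglog(iv$p0),
              log_shape = log(iv$shape), log_scale = log(iv$scale),
              if (p_lat) stats::setNames(rep(0, p_lat), colnames(lat$X)))
    Xl <- lat$X
    negll <- function(par) {
      theta_i <- exp(par[1L] +
                       if (p_lat) drop(Xl %*% par[4:(3 + p_lat)]) else 0)
      ll <- .ll_nonmixture_core(y, d, theta_i, exp(par[2L]), exp(par[3L]))
      if (!is.finite(ll)) 1e10 else -ll
    }
  } else {
    u <- log(y)
    bas <- .spline_eval(u, spec$spline)
    nb <- ncol(bas$basis)
    # initial spline coefficients from a cloglog regression on the KM curve
    curve <- km_estimate(cohort)
    ev <- curve$n_event > 0 & curve$surv > 0 & curve$surv < 1
    g0 <- tryCatch({
      z <- log(-log(curve$surv[ev]))
      bb <- .spline_eval(log(curve$time[ev]), spec$spline)$basis
      stats::coef(stats::lm(z ~ bb))
    }, error = function(e) NULL)
    if (is.null(g0) || anyNA(g0)) {
      g0 <- c(.cloglog(iv$p0), rep(0.1, nb))
    }
    par0 <- c(stats::setNames(g0, c("gamma0", paste0("gamma", seq_len(nb)))),
              if (p_lat) stats::setNames(rep(0, p_lat), colnames(lat$X)))
    Xl <- lat$X
    negll <- function(par) {
      lp <- if (p_lat) drop(Xl %*% par[(nb + 2L):(nb + 1L + p_lat)])
            else rep(0, length(y))
      ll <- .ll_flexible_core(u, d, bas$basis, bas$deriv,
                              par[1:(nb + 1L)], lp)
      if (!is.finite(ll)) 1e10 else -ll
    }
    # soft-barrier surrogate: negative fitted hazards at events are
    # penalized quadratically instead of walling the likelihood at -Inf,
    # which lets a quasi-Newton step walk an invalid start back into the
    # admissible region
    ev <- d == 1
    negll_soft <- function(par) {
      g <- par[1:(nb + 1L)]
      lp <- if (p_lat) drop(Xl %*% par[(nb + 2L):(nb + 1L + p_lat)])
            else rep(0, length(y))
      s <- g[1L] + drop(bas$basis %*% g[-1L]) + lp
      sprime <- drop(bas$deriv %*% g[-1L])
      pen <- 1e4 * sum(pmax(1e-4 - sprime[ev], 0)^2)
      ll <- sum(log(pmax(sprime[ev], 1e-8)) - u[ev] + s[ev]) -
        sum(exp(pmin(s, 30)))
      if (!is.finite(ll)) 1e10 else -ll + pen
    }
  }

  if (!is.null(init)) {
    if (length(init) != length(par0)) {
      stop("init must have length ", length(par0))
    }
    par0 <- stats::setNames(as.numeric(init), names(par0))
  }

  do_opt <- function(p0) {
    if (family == "flexible" && negll(p0) >= 1e10) {
      p0 <- stats::optim(p0, negll_soft, method = "BFGS",
                         control = list(maxit = 200))$par
    }
    stats::optim(p0, negll, method = "BFGS", hessian = FALSE,
                 control = list(maxit = max_iter, reltol = reltol))
  }
  opt <- do_opt(par0)
  restarts <- 0L
  if (opt$convergence != 0 || opt$value >= 1e10) {
    for (i in seq_len(multistart)) {
      set.seed(seed + i)
      cand <- tryCatch(
        do_opt(par0 * (1 + stats::rnorm(length(par0), 0, 0.2)) +
                 stats::rnorm(length(par0), 0, 0.05)),
        error = function(e) NULL)
      restarts <- i
      if (!is.null(cand) && cand$value < opt$value) opt <- cand
      if (opt$convergence == 0 && opt$value < 1e10) break
    }
  }

  hess <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
  vcov <- NULL
  vcov_ok <- FALSE
  if (!is.null(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov)) {
      evs <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values
      vcov_ok <- all(is.finite(evs)) && min(evs) > -1e-8 * max(abs(evs))
      dimnames(vcov) <- list(names(par0), names(par0))
    }
  }
  if (is.null(vcov)) {
    vcov <- matrix(NA_real_, length(par0), length(par0),
                   dimnames = list(names(par0), names(par0)))
  }

  structure(list(
    spec = spec,
    par = stats::setNames(opt$par, names(par0)),
    vcov = vcov, vcov_ok = vcov_ok,
    loglik = -opt$value,
    k = length(par0),
    n = length(y), n_event = sum(d),
    convergence = list(code = opt$convergence, restarts = restarts,
                       converged = opt$convergence == 0 && opt$value < 1e10),
    design = list(latency_map = lat$map, incidence_map = inc$map,
                  latency_cols = colnames(lat$X),
                  incidence_cols = colnames(inc$X)),
    schema = attr(cohort, "schema")
  ), class = "cure_model_fit")
}

#' @export
print.cure_model_fit <- function(x, ...) {
  ic <- information_criteria(x)
  cat(sprintf("%s cure model: n = %d (%d events), k = %d\n",
              x$spec$family, x$n, x$n_event, x$k))
  cat(sprintf("  log-likelihood = %.4f, AIC = %.2f, BIC = %.2f\n",
              x$loglik, ic[["AIC"]], ic[["BIC"]]))
  cf <- tryCatch(cure_fraction(x), error = function(e) NULL)
  if (!is.null(cf)) {
    cat(sprintf("  cure fraction (reference profile) = %.3f (%.3f, %.3f)\n",
                cf$estimate, cf$lower, cf$upper))
  }
  if (!x$convergence$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
logLik.cure_model_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

# Profile row (named covariate values) -> design vector on given columns.
.profile_vector <- function(cols, schema, profile) {
  v <- stats::setNames(rep(0, length(cols)), cols)
  if (is.null(profile) || length(cols) == 0L) return(v)
  for (nm in names(profile)) {
    if (!nm %in% names(schema)) stop("profile names unknown covariate: ", nm)
    if (schema[[nm]]$kind == "continuous") {
      if (nm %in% cols) v[nm] <- as.numeric(profile[[nm]])
    } else {
      cn <- paste0(nm, ":", profile[[nm]])
      if (cn %in% cols) v[cn] <- 1
    }
  }
  v
}

#' Cure fraction implied by a fitted model
#'
#' For the flexible family the cure fraction is the survival plateau
#' exp(-exp(eta)) with eta the linear predictor at (and beyond) the last
#' knot; for the mixture family it is the incidence parameter at the
#' profile; for the non-mixture family it is exp(-theta(x)). The Wald
#' confidence interval is formed on the linear-predictor (link) scale and
#' transformed, so the bounds always stay inside (0, 1).
#'
#' @param fit a [fit_cure_model()] result.
#' @param profile named list of covariate values (continuous value or
#'   category label); defaults to zero / reference levels.
#' @param conf_level confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, `eta`, `se_eta` and
#'   `ci_available`.
#' @export
cure_fraction <- function(fit, profile = NULL, conf_level = 0.95) {
  stopifnot(inherits(fit, "cure_model_fit"))
  fam <- fit$spec$family
  par <- fit$par
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (fam == "flexible") {
    if (!isTRUE(fit$spec$spline$cure_constraint)) {
      stop("cure fraction requires the cure-constrained spline basis")
    }
    km_knot <- max(fit$spec$spline$knots)
    bvals <- .spline_eval(km_knot, fit$spec$spline)$basis[1L, ]
    xv <- .profile_vector(fit$design$latency_cols, fit$schema, profile)
    a <- c(1, bvals, xv)
    link <- "cloglog"
  } else if (fam == "mixture") {
    xv <- .profile_vector(fit$design$incidence_cols, fit$schema, profile)
    a <- rep(0, length(par))
    a[1L] <- 1
    if (length(xv)) a[1L + seq_along(xv)] <- xv
    link <- fit$spec$cure_link
  } else {
    xv <- .profile_vector(fit$design$latency_cols, fit$schema, profile)
    a <- c(1, 0, 0, xv)
    link <- "cloglog"
  }
  stopifnot(length(a) == length(par))
  eta <- sum(a * par)
  est <- .inv_link(eta, link)
  ci_ok <- isTRUE(fit$vcov_ok) && !anyNA(fit$vcov)
  if (ci_ok) {
    se <- sqrt(drop(t(a) %*% fit$vcov %*% a))
    bounds <- sort(.inv_link(c(eta - zq * se, eta + zq * se), link))
    lower <- bounds[1L]; upper <- bounds[2L]
  } else {
    se <- NA_real_; lower <- NA_real_; upper <- NA_real_
  }
  list(estimate = est, lower = lower, upper = upper,
       eta = eta, se_eta = se, ci_available = ci_ok)
}

#' Hazard-ratio and cure-ratio transforms of a log hazard-ratio
#'
#' `hazard_ratio(beta)` is `exp(beta)`; `cure_ratio(beta)` is the
#' complementary log-log transform `exp(-exp(beta))`, the per-category
#' "cure ratio" reported alongside coefficient tables (note it deliberately
#' omits the baseline plateau; the profile-specific cure fraction is
#' available from [cure_fraction()]).
#'
#' @param beta log hazard-ratio value(s).
#' @return Numeric vector.
#' @export
hazard_ratio <- function(beta) exp(beta)

#' @rdname hazard_ratio
#' @export
cure_ratio <- function(beta) exp(-exp(beta))

#' Coefficient / hazard-ratio / cure-ratio table of a fitted cure model
#'
#' One row per covariate coefficient: estimate beta on the log hazard-ratio
#' scale, standard error, Wald z and p-value, HR = exp(beta) with its
#' normal-theory confidence interval, and the cure ratio exp(-exp(beta)).
#' Reference categories are included with beta = 0, HR = 1 and a degenerate
#' interval.
#'
#' @param fit a [fit_cure_model()] result.
#' @param which `"latency"` (default) or `"incidence"` (mixture family).
#' @param conf_level confidence level (default 0.95, using the 1.96 normal
#'   quantile).
#' @return Data frame of class `effect_table`.
#' @export
effect_table <- function(fit, which = c("latency", "incidence"),
                         conf_level = 0.95) {
  stopifnot(inherits(fit, "cure_model_fit"))
  which <- match.arg(which)
  map <- if (which == "latency") fit$design$latency_map
         else fit$design$incidence_map
  cols <- if (which == "latency") fit$design$latency_cols
          else fit$design$incidence_cols
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  par_names <- if (which == "incidence") paste0("cure_", cols) else cols
  rows <- list()
  for (cov in names(map)) {
    sp <- fit$schema[[cov]]
    if (sp$kind == "categorical") {
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cov, level = sp$reference, reference = TRUE,
        coefficient = 0, se = 0, z = NA_real_, p_value = NA_real_,
        hr = 1, hr_lower = 1, hr_upper = 1, cure_ratio = NA_real_,
        stringsAsFactors = FALSE)
    }
    for (cn in map[[cov]]) {
      pn <- if (which == "incidence") paste0("cure_", cn) else cn
      beta <- unname(fit$par[pn])
      se <- if (isTRUE(fit$vcov_ok)) sqrt(fit$vcov[pn, pn]) else NA_real_
      z <- beta / se
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cov,
        level = if (grepl(":", cn, fixed = TRUE))
                  sub("^[^:]*:", "", cn) else "",
        reference = FALSE,
        coefficient = beta, se = se, z = z,
        p_value = 2 * stats::pnorm(-abs(z)),
        hr = exp(beta),
        hr_lower = exp(beta - zq * se),
        hr_upper = exp(beta + zq * se),
        cure_ratio = cure_ratio(beta),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(covariate = character(0), level = character(0),
               reference = logical(0), coefficient = numeric(0),
               se = numeric(0), z = numeric(0), p_value = numeric(0),
               hr = numeric(0), hr_lower = numeric(0),
               hr_upper = numeric(0), cure_ratio = numeric(0))
  class(out) <- c("effect_table", "data.frame")
  out
}

# Natural-scale parameters of a fit.
.natural_params <- function(fit) {
  par <- fit$par
  fam <- fit$spec$family
  if (fam == "mixture") {
    p_inc <- length(fit$design$incidence_cols)
    list(pi0 = .inv_link(unname(par[1L]), fit$spec$cure_link),
         eta0 = unname(par[1L]),
         b_inc = if (p_inc) unname(par[2:(1 + p_inc)]) else numeric(0),
         shape = exp(unname(par[p_inc + 2L])),
         scale = exp(unname(par[p_inc + 3L])),
         b_lat = unname(par[-seq_len(p_inc + 3L)]))
  } else if (fam == "nonmixture") {
    list(eta0 = unname(par[1L]),
         shape = exp(unname(par[2L])), scale = exp(unname(par[3L])),
         b_lat = unname(par[-(1:3)]))
  } else {
    nb <- fit$spec$spline$n_basis
    list(gamma = unname(par[1:(nb + 1L)]),
         b_lat = unname(par[-(1:(nb + 1L))]))
  }
}

#' Population survival function of a fitted cure model
#'
#' Family-specific survival S_pop(t | profile): monotone non-increasing in
#' t, equal to 1 at t = 0 and bounded below by the profile's cure fraction
#' (the flexible fit is exactly flat beyond its last knot).
#'
#' @param fit a [fit_cure_model()] result.
#' @param t times in years (vectorized, non-negative).
#' @param profile named list of covariate values (defaults to
#'   zero / reference).
#' @return Numeric vector of survival probabilities.
#' @export
predict_survival <- function(fit, t, profile = NULL) {
  stopifnot(inherits(fit, "cure_model_fit"))
  if (any(t < 0)) stop("t must be non-negative")
  np <- .natural_params(fit)
  xl <- .profile_vector(fit$design$latency_cols, fit$schema, profile)
  lp <- sum(xl * np$b_lat)
  fam <- fit$spec$family
  out <- numeric(length(t))
  pos <- t > 0
  if (fam == "mixture") {
    xi <- .profile_vector(fit$design$incidence_cols, fit$schema, profile)
    pi_x <- .inv_link(np$eta0 + sum(xi * np$b_inc), fit$spec$cure_link)
    Su <- exp(-(t[pos] / np$scale)^np$shape * exp(lp))
    out[pos] <- pi_x + (1 - pi_x) * Su
  } else if (fam == "nonmixture") {
    theta <- exp(np$eta0 + lp)
    Fu <- -expm1(-(t[pos] / np$scale)^np$shape)
    out[pos] <- exp(-theta * Fu)
  } else {
    bas <- .spline_eval(log(t[pos]), fit$spec$spline)$basis
    s <- np$gamma[1L] + drop(bas %*% np$gamma[-1L]) + lp
    out[pos] <- exp(-exp(s))
  }
  out[!pos] <- 1
  out
}
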