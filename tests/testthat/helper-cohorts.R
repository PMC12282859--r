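# Shared fixtures and independent oracles, all built in code.

# Minimal cohort from raw vectors.
toy_cohort <- function(time, event, ...) {
  extra <- list(...)
  df <- data.frame(id = seq_along(time), time_years = time, event = event)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  as_cohort(df)
}

# Brute-force product-limit estimator: explicit loop over risk sets at
# distinct event times, events before censorings at ties. Independent of
# km_estimate()'s survfit route.
brute_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  S <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t_i <- ev_times[i]
    n_i <- sum(time > t_i | (time == t_i))          # at risk just before t_i
    d_i <- sum(time == t_i & event == 1)
    s <- s * (1 - d_i / n_i)
    S[i] <- s
  }
  data.frame(time = ev_times, surv = S)
}

# Random small right-censored cohort for property loops.
random_cohort <- function(n, seed, cens_rate = 0.5) {
  set.seed(seed)
  t_ev <- rweibull(n, shape = runif(1, 0.7, 2), scale = runif(1, 0.5, 4))
  c_ev <- rexp(n, cens_rate)
  toy_cohort(pmin(t_ev, c_ev), as.integer(t_ev <= c_ev))
}

# Closed-form Weibull log-likelihood (independent oracle for reductions).
weibull_loglik <- function(time, event, shape, scale) {
  sum(event * dweibull(time, shape, scale, log = TRUE) +
        (1 - event) * pweibull(time, shape, scale, lower.tail = FALSE,
                               log.p = TRUE))
}

# Small registry-like cohort generated from the packaged default profile.
default_cohort <- function(n = 1500, seed = 1) {
  cfg <- paper_default_config(n_subjects = n)
  generate_cohort(cfg, seed = seed)
}
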