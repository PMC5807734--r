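# Fixture builders shared across the suite.

# Minimal subjects row with defaults; covariates appended as extra cols.
subj_row <- function(id, time, status = "censored", in_situ = FALSE,
                     metastatic = FALSE, mets_flag = FALSE, ...) {
  n <- length(id)
  data.frame(subject_id = id, terminal_time = rep_len(time, n),
             terminal_status = rep_len(status, n),
             in_situ = rep_len(in_situ, n),
             metastatic_dx = rep_len(metastatic, n),
             mets_at_death_only = rep_len(mets_flag, n),
             ..., stringsAsFactors = FALSE)
}

event_row <- function(id, time, type = "metastasis", confirmed = TRUE,
                      type_known = TRUE) {
  data.frame(subject_id = id, time = time, type = type,
             confirmed = confirmed, type_known = type_known,
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(subject_id = character(), time = numeric(),
             type = character(), confirmed = logical(),
             type_known = logical(), stringsAsFactors = FALSE)
}

# Small two-group cohort scenario for fitting tests: one binary covariate
# acting on both submodels.
toy_scenario <- function(n = 300, theta = 1, alpha = 1.5,
                         hr_rec = 2, hr_death = 2, horizon = 12,
                         dropout = c(1, 14), rate_R = 0.18,
                         rate_D = 0.03) {
  scenario(n, theta, alpha,
           weibull_baseline(1, 1 / rate_R), weibull_baseline(1, 1 / rate_D),
           covariates = list(scenario_covariate(
             "group", c("a", "b"), c(0.5, 0.5),
             log_hr_recurrence = c(b = log(hr_rec)),
             log_hr_death = c(b = log(hr_death)))),
           horizon = horizon, dropout = dropout)
}

# Brute-force marginal log-likelihood by adaptive integration of the
# untransformed integrand against the gamma frailty density.
oracle_subject_loglik <- function(params, s) {
  AR <- cumulative_baseline_hazard(params$baseline_R, s$T) *
    exp(sum(s$x_R * params$beta_R))
  AD <- cumulative_baseline_hazard(params$baseline_D, s$T) *
    exp(sum(s$x_D * params$beta_D))
  lr <- (if (s$J) sum(log(baseline_hazard(params$baseline_R,
                                          s$event_times))) else 0) +
    s$J * sum(s$x_R * params$beta_R)
  ld <- if (s$delta) log(baseline_hazard(params$baseline_D, s$T)) +
    sum(s$x_D * params$beta_D) else 0
  f <- function(u) u^(s$J + params$alpha * s$delta) *
    exp(-u * AR - u^params$alpha * AD) *
    gamma_frailty_density(u, params$theta)
  I <- NULL
  for (tol in c(1e-11, 1e-10, 1e-9)) {
    I <- tryCatch(stats::integrate(f, 0, Inf, rel.tol = tol,
                                   abs.tol = 0)$value,
                  error = function(e) NULL)
    if (!is.null(I)) break
  }
  if (is.null(I))  # pathological draw: same integral on a split range
    I <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0)$value +
      stats::integrate(f, 1, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  lr + ld + log(I)
}

# Brute-force dynamic prediction by adaptive integration.
oracle_predict <- function(params, xR, xD, t, w, J, kind) {
  etaR <- sum(xR * params$beta_R)
  etaD <- sum(xD * params$beta_D)
  LRt <- cumulative_baseline_hazard(params$baseline_R, t) * exp(etaR)
  SD <- function(s, u) exp(-u^params$alpha *
    cumulative_baseline_hazard(params$baseline_D, s) * exp(etaD))
  wt <- if (kind == "P1") function(u) u^J * exp(-u * LRt)
        else function(u) 1
  num <- stats::integrate(function(u) (SD(t, u) - SD(t + w, u)) * wt(u) *
    gamma_frailty_density(u, params$theta), 0, Inf,
    rel.tol = 1e-11, abs.tol = 0)$value
  den <- stats::integrate(function(u) SD(t, u) * wt(u) *
    gamma_frailty_density(u, params$theta), 0, Inf,
    rel.tol = 1e-11, abs.tol = 0)$value
  num / den
}

# A random valid subject draw for oracle comparisons.
random_subject_case <- function() {
  th <- runif(1, 0.05, 2)
  al <- runif(1, -0.5, 4.5)
  bR <- weibull_baseline(runif(1, 0.7, 1.8), runif(1, 3, 12))
  bD <- weibull_baseline(runif(1, 0.7, 1.8), runif(1, 8, 40))
  J <- sample(0:4, 1)
  del <- rbinom(1, 1, 0.5)
  T <- runif(1, 1, 12)
  x <- rbinom(1, 1, 0.5)
  list(params = joint_frailty_params(th, al, rnorm(1, 0, 0.5),
                                     rnorm(1, 0, 0.5), bR, bD),
       subject = list(J = J, delta = del, T = T,
                      event_times = sort(runif(J, 0.05, T)),
                      x_R = x, x_D = x))
}
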