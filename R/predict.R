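#' Covariate risk profiles
#'
#' A risk profile names one category per covariate of the cohort
#' codebook.  Three presets are packaged for the breast-cancer codebook:
#' `"low"` (hormone-receptor positive, well differentiated, small tumor,
#' no nodal involvement, recent MHT use, never smoker, diagnosis
#' 2004-2008, age < 50, postmenopausal with < 5 years of MHT),
#' `"medium"` (ER+/PR-, moderately differentiated, tumor >= 2 cm, no
#' nodal involvement, recent MHT use, ex-smoker, diagnosis 1995-1999,
#' age 50-60, premenopausal) and `"high"` (double receptor negative,
#' poorly differentiated, tumor >= 2 cm, nodal involvement, no MHT,
#' current smoker, diagnosis 1990-1994, age >= 70, postmenopausal
#' without MHT).
#'
#' @param profile `"low"`, `"medium"`, `"high"`, or a named character
#'   vector/list of covariate categories.
#' @param codebook codebook to validate against (defaults to the
#'   breast-cancer codebook, see [breast_cohort_codebook()]).
#' @return an object of class `jf_profile` (named character vector).
#' @export
risk_profile <- function(profile = c("low", "medium", "high"),
                         codebook = breast_cohort_codebook()) {
  presets <- list(
    low = c(receptors = "pos_pos", grade = "well", size = "lt2",
            nodal = "no", mht = "yes", smoking = "never",
            year_dx = "2004_2008", age_dx = "lt50",
            menopause = "post_mht_lt5"),
    medium = c(receptors = "pos_neg", grade = "moderate", size = "ge2",
               nodal = "no", mht = "yes", smoking = "ex",
               year_dx = "1995_1999", age_dx = "50_60",
               menopause = "pre"),
    high = c(receptors = "neg_neg", grade = "poor", size = "ge2",
             nodal = "yes", mht = "no", smoking = "current",
             year_dx = "1990_1994", age_dx = "ge70",
             menopause = "post_no_mht"))
  if (is.character(profile) && length(profile) == 1L &&
      profile %in% names(presets)) {
    x <- presets[[profile]]
  } else {
    x <- unlist(profile)
    if (is.null(names(x)) || any(names(x) == ""))
      stop("custom profiles must be fully named")
  }
  for (v in names(x)) {
    if (!v %in% names(codebook))
      stop("profile covariate '", v, "' is not in the codebook")
    if (!x[[v]] %in% codebook[[v]])
      stop("profile category '", x[[v]], "' is not a level of '", v, "'")
  }
  structure(x, class = "jf_profile")
}

profile_design_row <- function(fit, profile) {
  df <- as.data.frame(as.list(unclass(profile)), stringsAsFactors = FALSE)
  need <- unique(c(fit$design$recurrent, fit$design$death))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile does not set covariate(s): ", paste(miss, collapse = ", "))
  list(xR = drop(design_matrix(fit$design, df, "recurrent")),
       xD = drop(design_matrix(fit$design, df, "death")))
}

# Core dynamic-prediction integral.  Conditional on frailty u and
# covariates, the death survival is S_D(s|u) = exp(-u^alpha Lambda_D(s)
# e^eta_D).  P1 conditions on surviving to t with exactly J recurrences
# (posterior frailty weight u^J exp(-u Lambda_R(t) e^eta_R)); P2
# conditions on survival to t only.  Both are ratios of integrals of the
# form int u^(a-1) exp(-b u - c u^alpha) du, so
#   P = 1 - I(c at t+w) / I(c at t),
# with the integrals computed on the log scale by the same adaptive
# Gauss-Hermite scheme as the likelihood.  Returns one probability per
# window.
predict_prob_core <- function(params, xR, xD, t, w, J, kind, nodes = 32) {
  stopifnot(all(w >= 0), t >= 0, J >= 0)
  etaR <- if (length(params$beta_R)) sum(xR * params$beta_R) else 0
  etaD <- if (length(params$beta_D)) sum(xD * params$beta_D) else 0
  eD <- exp(etaD)
  LDt <- cumulative_baseline_hazard(params$baseline_D, t) * eD
  LDw <- cumulative_baseline_hazard(params$baseline_D, t + w) * eD
  if (params$theta <= 0)
    return(pmin(pmax(-expm1(-(LDw - LDt)), 0), 1))
  ish <- 1 / params$theta
  if (kind == "P1") {
    a <- ish + J
    b <- ish + cumulative_baseline_hazard(params$baseline_R, t) * exp(etaR)
  } else {
    a <- ish
    b <- ish
  }
  L <- log_gamma_power_integral(a, b, c(LDt, LDw), params$alpha,
                                nodes = nodes, method = "adaptive")
  pmin(pmax(-expm1(L[-1] - L[1]), 0), 1)
}

check_prediction_support <- function(fit, t, w) {
  if (!is.null(fit$max_time) && t + max(w) > fit$max_time)
    warning("prediction horizon ", t + max(w),
            " years exceeds the observed follow-up range (",
            signif(fit$max_time, 4),
            " years); baseline hazards are extrapolated")
}

#' Dynamic prediction of death given the recurrence history (P1)
#'
#' Probability of death in the window `(t, t + w]` for a subject with the
#' given covariate profile who is alive at the landmark `t` with exactly
#' `events` observed recurrences.  Under the calendar-timescale model the
#' prediction depends on the history only through the number of
#' recurrences and the landmark; recurrence times, if supplied, are
#' validated but do not change the value.
#'
#' @param fit a converged `jf_fit`.
#' @param profile a `jf_profile` (or preset name).
#' @param t landmark time in years since diagnosis (>= 0).
#' @param window prediction window(s) in years (> 0, may be a vector).
#' @param events number of recurrences observed before `t` (J).
#' @param recurrence_times optional strictly increasing times of the
#'   `events` recurrences, all at most `t`.
#' @param nodes quadrature nodes.
#' @return an object of class `jf_prediction` with `probability` (one
#'   value per window).
#' @export
predict_p1 <- function(fit, profile, t, window, events = 0,
                       recurrence_times = NULL, nodes = 32) {
  pred_common(fit, profile, t, window, events, recurrence_times,
              kind = "P1", nodes = nodes)
}

#' Dynamic prediction of death ignoring the recurrence history (P2)
#'
#' Same window probability as [predict_p1()] but conditioning only on
#' survival to the landmark, marginally over the recurrence history; the
#' result does not depend on `events`.
#'
#' @inheritParams predict_p1
#' @export
predict_p2 <- function(fit, profile, t, window, nodes = 32) {
  pred_common(fit, profile, t, window, events = 0,
              recurrence_times = NULL, kind = "P2", nodes = nodes)
}

pred_common <- function(fit, profile, t, window, events, recurrence_times,
                        kind, nodes) {
  stopifnot(inherits(fit, "jf_fit"))
  if (fit$convergence$status != "converged")
    stop("model did not converge; no predictions available")
  if (is.character(profile)) profile <- risk_profile(profile,
                                                     fit$design$codebook)
  stopifnot(all(window >= 0), t >= 0, events >= 0)
  if (!is.null(recurrence_times)) {
    if (length(recurrence_times) != events)
      stop("recurrence_times has length ", length(recurrence_times),
           " but events = ", events)
    if (length(recurrence_times) &&
        (is.unsorted(recurrence_times, strictly = TRUE) ||
         any(recurrence_times > t) || any(recurrence_times <= 0)))
      stop("recurrence_times must be strictly increasing, positive and <= t")
  }
  check_prediction_support(fit, t, window)
  dx <- profile_design_row(fit, profile)
  p <- predict_prob_core(fit$params, dx$xR, dx$xD, t, window, events,
                         kind, nodes)
  structure(list(kind = kind, t = t, window = window, events = events,
                 probability = p, profile = profile,
                 ci_low = NULL, ci_high = NULL),
            class = "jf_prediction")
}

#' Monte-Carlo confidence interval for a dynamic prediction
#'
#' Draws parameter vectors on the estimation scale from the asymptotic
#' normal distribution of the estimator (mean = fitted vector,
#' covariance = inverse observed information), recomputes the prediction
#' for every draw, and returns the 2.5th and 97.5th percentiles.  A
#' non-positive-semidefinite covariance is repaired by clipping negative
#' eigenvalues to zero, with a warning.
#'
#' @inheritParams predict_p1
#' @param kind `"P1"` or `"P2"`.
#' @param n_draws number of Monte-Carlo draws (>= 100).
#' @param seed RNG seed (draws are reproducible given the seed).
#' @return a `jf_prediction` with `ci_low`/`ci_high` per window.
#' @export
prediction_confidence_interval <- function(fit, profile, t, window,
                                           events = 0, kind = c("P1", "P2"),
                                           n_draws = 500, seed = 1,
                                           nodes = 32) {
  kind <- match.arg(kind)
  stopifnot(inherits(fit, "jf_fit"), n_draws >= 100)
  if (is.null(fit$vcov))
    stop("covariance matrix unavailable; cannot compute intervals")
  point <- pred_common(fit, profile, t, window, events, NULL, kind, nodes)
  vc <- fit$vcov
  ev <- eigen(vc, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values), 1))) {
    warning("covariance matrix is not positive semidefinite; ",
            "negative eigenvalues clipped to zero")
  }
  vals <- pmax(ev$values, 0)
  vc <- ev$vectors %*% (vals * t(ev$vectors))
  if (is.character(profile)) profile <- risk_profile(profile,
                                                     fit$design$codebook)
  dx <- profile_design_row(fit, profile)
  draws <- with_private_seed(seed,
    MASS::mvrnorm(n_draws, mu = fit$par, Sigma = vc))
  P <- matrix(NA_real_, n_draws, length(window))
  for (d in seq_len(n_draws)) {
    pp <- unpack_par(draws[d, ], fit$spec)
    P[d, ] <- predict_prob_core(
      list(theta = pp$theta, alpha = pp$alpha, beta_R = pp$beta_R,
           beta_D = pp$beta_D, baseline_R = pp$baseline_R,
           baseline_D = pp$baseline_D),
      dx$xR, dx$xD, t, window, events, kind, nodes)
  }
  point$ci_low <- apply(P, 2, stats::quantile, probs = 0.025, names = FALSE)
  point$ci_high <- apply(P, 2, stats::quantile, probs = 0.975, names = FALSE)
  point$n_draws <- n_draws
  point$seed <- seed
  point
}

#' Prediction curve over a grid of windows
#'
#' Tidy data frame of window probabilities (and optional Monte-Carlo
#' intervals) for one profile and recurrence count, suitable for
#' plotting dynamic-prediction curves.
#'
#' @inheritParams prediction_confidence_interval
#' @param windows vector of windows (years).
#' @param ci compute Monte-Carlo intervals.
#' @return data.frame with columns `t`, `window`, `events`, `kind`,
#'   `probability` and, if requested, `ci_low`, `ci_high`.
#' @export
prediction_curve <- function(fit, profile, t, windows, events = 0,
                             kind = c("P1", "P2"), ci = FALSE,
                             n_draws = 500, seed = 1, nodes = 32) {
  kind <- match.arg(kind)
  pr <- if (ci)
    prediction_confidence_interval(fit, profile, t, windows, events,
                                   kind, n_draws, seed, nodes)
  else pred_common(fit, profile, t, windows, events, NULL, kind, nodes)
  out <- data.frame(t = t, window = windows, events = events, kind = kind,
                    probability = pr$probability)
  if (ci) {
    out$ci_low <- pr$ci_low
    out$ci_high <- pr$ci_high
  }
  out
}

#' Per-subject predictions for a cohort at a landmark
#'
#' Window death probabilities for every subject still at risk (alive and
#' under follow-up) at the landmark, using each subject's covariates and
#' observed number of recurrences up to the landmark.  Used by the
#' prediction-error machinery.
#'
#' @param fit a converged `jf_fit` (joint or frailty-free).
#' @param counting the `jf_counting` the predictions refer to.
#' @param t landmark time (years).
#' @param window single prediction window (years).
#' @param kind `"P1"`, `"P2"`, or `"free"` (frailty-free fit; history
#'   ignored).
#' @return data.frame with `subject_id`, `events`, `probability`.
#' @export
predict_cohort <- function(fit, counting, t, window,
                           kind = c("P1", "P2", "free")) {
  kind <- match.arg(kind)
  stopifnot(inherits(fit, "jf_fit"), inherits(counting, "jf_counting"),
            length(window) == 1L)
  at_risk <- which(counting$subjects$T > t)
  if (!length(at_risk)) stop("no subjects at risk at t = ", t)
  Jt <- vapply(at_risk, function(i)
    sum(counting$ev_i == i & counting$ev_t <= t), integer(1))
  XR <- counting$XR[at_risk, , drop = FALSE]
  XD <- counting$XD[at_risk, , drop = FALSE]
  core_kind <- if (kind == "P1") "P1" else "P2"
  key <- paste(if (kind == "P1") Jt else 0L,
               apply(cbind(XR, XD), 1, paste, collapse = ","))
  prob <- numeric(length(at_risk))
  for (g in unique(key)) {
    idx <- which(key == g)
    i1 <- idx[1]
    prob[idx] <- predict_prob_core(fit$params, XR[i1, ], XD[i1, ], t,
                                   window, Jt[i1], core_kind, fit$nodes)
  }
  data.frame(subject_id = counting$subjects$subject_id[at_risk],
             events = Jt, probability = prob, stringsAsFactors = FALSE)
}

#' @export
print.jf_prediction <- function(x, ...) {
  cat(sprintf("%s prediction at landmark t = %g years, J = %d\n",
              x$kind, x$t, x$events))
  df <- data.frame(window = x$window,
                   probability = round(x$probability, 4))
  if (!is.null(x$ci_low)) {
    df$ci_low <- round(x$ci_low, 4)
    df$ci_high <- round(x$ci_high, 4)
  }
  print(df, row.names = FALSE)
  invisible(x)
}
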