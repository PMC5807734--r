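#' Joint frailty model parameters
#'
#' Parameter container for the joint model of a recurrent-event process
#' and a terminal event.  Conditional on a subject-level frailty
#' `u ~ Gamma(mean 1, variance theta)`, the recurrence intensity is
#' `u * r0(t) * exp(beta_R' x_R)` and the death hazard is
#' `u^alpha * l0(t) * exp(beta_D' x_D)`.  `theta = 0` denotes the
#' degenerate frailty-free limit (`u` identically 1), in which `alpha`
#' plays no role.
#'
#' @param theta frailty variance, >= 0.
#' @param alpha frailty power on the death hazard (any real).
#' @param beta_R named numeric vector of recurrence log-hazard ratios.
#' @param beta_D named numeric vector of death log-hazard ratios.
#' @param baseline_R,baseline_D `jf_baseline` objects for the recurrence
#'   and death baseline hazards.
#' @return an object of class `jf_params`.
#' @export
joint_frailty_params <- function(theta, alpha, beta_R, beta_D,
                                 baseline_R, baseline_D) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            all(is.finite(beta_R)), all(is.finite(beta_D)),
            inherits(baseline_R, "jf_baseline"),
            inherits(baseline_D, "jf_baseline"))
  structure(list(theta = theta, alpha = alpha,
                 beta_R = beta_R, beta_D = beta_D,
                 baseline_R = baseline_R, baseline_D = baseline_D),
            class = "jf_params")
}

# ---- vectorized marginal log-likelihood -----------------------------------

# dat: list(n, J, delta, T, ev_t, ev_i, XR, XD) as built by
# build_counting_process().  Returns the vector of per-subject marginal
# log-likelihood contributions.
#
# The frailty integral for a subject with J recurrences and death
# indicator d is
#   int u^(1/theta + J + alpha*d - 1) exp(-u(1/theta + A_R)) exp(-u^alpha A_D) du
#     / (Gamma(1/theta) theta^(1/theta)),
# evaluated by log_gamma_power_integral() (exact closed forms at alpha
# in {0, 1} and A_D = 0; otherwise mode-matched Laguerre or adaptive
# log-scale quadrature depending on `method`).
marginal_loglik_vec <- function(dat, theta, alpha, beta_R, beta_D,
                                baseline_R, baseline_D, nodes = 64,
                                method = "fixed") {
  n <- dat$n
  etaR <- if (length(beta_R)) drop(dat$XR %*% beta_R) else numeric(n)
  etaD <- if (length(beta_D)) drop(dat$XD %*% beta_D) else numeric(n)
  AR <- cumulative_baseline_hazard(baseline_R, dat$T) * exp(etaR)
  AD <- cumulative_baseline_hazard(baseline_D, dat$T) * exp(etaD)
  slr <- numeric(n)
  if (length(dat$ev_t)) {
    agg <- rowsum(log_baseline_hazard(baseline_R, dat$ev_t), dat$ev_i)
    slr[as.integer(rownames(agg))] <- agg[, 1]
  }
  log_event <- slr + dat$J * etaR
  log_death <- ifelse(dat$delta > 0,
                      log_baseline_hazard(baseline_D, dat$T) + etaD, 0)
  if (theta <= 0)
    return(log_event + log_death - AR - AD)
  ish <- 1 / theta
  ll_int <- log_gamma_power_integral(a = ish + dat$J + alpha * dat$delta,
                                     b = ish + AR, c = AD, alpha = alpha,
                                     nodes = nodes, method = method)
  log_event + log_death - lgamma(ish) - ish * log(theta) + ll_int
}

#' Marginal log-likelihood contribution of one subject
#'
#' Integrates the subject's conditional likelihood over the gamma
#' frailty (`theta = 0` uses the exact frailty-free product form).
#'
#' @param params a `jf_params`.
#' @param subject list with `J`, `delta`, `T`, `event_times`, `x_R`,
#'   `x_D` (as returned by [subject_slice()]).
#' @param method `"adaptive"` (default; near machine precision) or
#'   `"fixed"` (the mode-matched Laguerre rule the optimizer uses).
#' @param nodes quadrature nodes for the fixed method.
#' @return the marginal log-likelihood contribution (scalar).
#' @export
subject_marginal_loglik <- function(params, subject,
                                    method = c("adaptive", "fixed"),
                                    nodes = 64) {
  method <- match.arg(method)
  stopifnot(inherits(params, "jf_params"))
  if (length(subject$event_times) != subject$J)
    stop("subject has J = ", subject$J, " but ",
         length(subject$event_times), " event times")
  if (subject$J > 0 &&
      (any(diff(subject$event_times) <= 0) ||
       any(subject$event_times > subject$T)))
    stop("invalid event times for subject")
  dat <- list(n = 1L, J = subject$J, delta = subject$delta, T = subject$T,
              ev_t = subject$event_times,
              ev_i = rep(1L, length(subject$event_times)),
              XR = matrix(subject$x_R, nrow = 1),
              XD = matrix(subject$x_D, nrow = 1))
  out <- marginal_loglik_vec(dat, params$theta, params$alpha,
                             params$beta_R, params$beta_D,
                             params$baseline_R, params$baseline_D,
                             nodes, method)
  if (!is.finite(out))
    stop("non-finite marginal log-likelihood for subject")
  out
}

#' Total marginal log-likelihood of a cohort
#'
#' @param params a `jf_params`.
#' @param counting a `jf_counting`.
#' @inheritParams subject_marginal_loglik
#' @return the summed marginal log-likelihood.
#' @export
joint_loglik <- function(params, counting, method = c("fixed", "adaptive"),
                         nodes = 64) {
  method <- match.arg(method)
  stopifnot(inherits(params, "jf_params"), inherits(counting, "jf_counting"))
  dat <- counting_dat(counting)
  sum(marginal_loglik_vec(dat, params$theta, params$alpha,
                          params$beta_R, params$beta_D,
                          params$baseline_R, params$baseline_D,
                          nodes, method))
}

counting_dat <- function(counting) {
  list(n = counting$n, J = counting$subjects$J,
       delta = counting$subjects$delta, T = counting$subjects$T,
       ev_t = counting$ev_t, ev_i = counting$ev_i,
       XR = counting$XR, XD = counting$XD)
}
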