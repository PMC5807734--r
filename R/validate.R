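#' Censoring survival function (reverse Kaplan-Meier)
#'
#' Kaplan-Meier estimate of the censoring survival function G, treating
#' censoring as the event and death as censoring.  Used to build inverse
#' probability of censoring weights.
#'
#' @param x a `jf_cohort` or `jf_counting`.
#' @return an object of class `jf_censoring` with step times and values.
#' @export
censoring_survival <- function(x) {
  if (inherits(x, "jf_cohort")) {
    T <- x$subjects$terminal_time
    cens <- as.integer(x$subjects$terminal_status == "censored")
  } else if (inherits(x, "jf_counting")) {
    T <- x$subjects$T
    cens <- 1L - x$subjects$delta
  } else stop("x must be a jf_cohort or jf_counting")
  if (!length(T)) stop("no subjects")
  sf <- survival::survfit(survival::Surv(T, cens) ~ 1)
  structure(list(time = sf$time, surv = sf$surv, n = length(T)),
            class = "jf_censoring")
}

#' Evaluate the censoring survival estimate
#'
#' @param G a `jf_censoring`.
#' @param s evaluation times.
#' @param left evaluate the left limit G(s-) instead of G(s).
#' @return values of the step function, starting at 1.
#' @export
censoring_survival_at <- function(G, s, left = FALSE) {
  stopifnot(inherits(G, "jf_censoring"))
  f <- stats::stepfun(G$time, c(1, G$surv), right = left)
  f(s)
}

#' @export
print.jf_censoring <- function(x, ...) {
  cat(sprintf("Reverse Kaplan-Meier censoring survival (%d subjects, %d steps)\n",
              x$n, length(x$time)))
  invisible(x)
}

#' IPCW expected prediction error (Brier score) at a landmark
#'
#' Weighted mean squared difference between the predicted window death
#' probability and the observed window outcome, over subjects at risk at
#' the landmark `t`: subjects dying in `(t, t + w]` contribute
#' `(1 - P)^2` with weight `G(t)/G(T-)`, subjects under follow-up at
#' `t + w` contribute `P^2` with weight `G(t)/G((t+w)-)`, and subjects
#' censored inside the window get weight zero.  Weights are normalized
#' by their sum.  With no censoring this reduces to the unweighted mean
#' squared error.
#'
#' @param predictions data.frame with `subject_id` and `probability`
#'   covering every subject at risk at `t` (as from [predict_cohort()]).
#' @param x the `jf_cohort` or `jf_counting` holding observed outcomes.
#' @param t landmark time (years).
#' @param window prediction window w (> 0, years).
#' @param G optional `jf_censoring`; estimated from `x` if omitted.
#' @return an object of class `jf_epe`: `epe`, `n_at_risk`, `n_deaths`,
#'   `sum_weights`, `effective_n`, `min_G`.
#' @export
expected_prediction_error <- function(predictions, x, t, window, G = NULL) {
  stopifnot(window > 0, t >= 0)
  if (inherits(x, "jf_cohort")) {
    subj <- data.frame(subject_id = x$subjects$subject_id,
                       T = x$subjects$terminal_time,
                       delta = as.integer(x$subjects$terminal_status == "death"),
                       stringsAsFactors = FALSE)
  } else if (inherits(x, "jf_counting")) {
    subj <- x$subjects[c("subject_id", "T", "delta")]
  } else stop("x must be a jf_cohort or jf_counting")
  if (is.null(G)) G <- censoring_survival(x)
  at <- subj[subj$T > t, , drop = FALSE]
  m <- match(at$subject_id, predictions$subject_id)
  if (anyNA(m))
    stop("predictions missing for subject(s) at risk: ",
         paste(utils::head(at$subject_id[is.na(m)], 3), collapse = ", "))
  P <- predictions$probability[m]
  died <- at$delta == 1 & at$T <= t + window
  followed <- at$T > t + window | (at$delta == 0 & at$T == t + window)
  Gt <- censoring_survival_at(G, t)
  if (Gt <= 0) stop("censoring survival is zero at the landmark t = ", t)
  W <- numeric(nrow(at))
  if (any(died)) {
    Gd <- censoring_survival_at(G, at$T[died], left = TRUE)
    if (any(Gd <= 0))
      stop("censoring survival is zero just before death time(s) ",
           paste(signif(utils::head(at$T[died][Gd <= 0], 3), 5),
                 collapse = ", "))
    W[died] <- Gt / Gd
  }
  if (any(followed)) {
    Gw <- censoring_survival_at(G, t + window, left = TRUE)
    if (Gw <= 0)
      stop("censoring survival is zero just before the horizon ",
           t + window)
    W[followed] <- Gt / Gw
  }
  D <- as.numeric(died)
  sw <- sum(W)
  if (sw <= 0) stop("all at-risk subjects censored inside the window")
  epe <- sum(W * (D - P)^2) / sw
  structure(list(epe = epe, t = t, window = window,
                 n_at_risk = nrow(at), n_deaths = sum(died),
                 sum_weights = sw, effective_n = sw^2 / sum(W^2),
                 min_G = min(c(if (any(died))
                   censoring_survival_at(G, at$T[died], left = TRUE),
                   censoring_survival_at(G, t + window, left = TRUE)))),
            class = "jf_epe")
}

#' @export
print.jf_epe <- function(x, ...) {
  cat(sprintf("IPCW prediction error at t = %g, w = %g: %.4f (%d at risk, %d deaths)\n",
              x$t, x$window, x$epe, x$n_at_risk, x$n_deaths))
  invisible(x)
}

#' Prediction-error curves for P1, P2 and a frailty-free comparator
#'
#' Computes the IPCW expected prediction error over a grid of windows for
#' the joint model used with the recurrence history (P1), the joint model
#' marginal over the history (P2), and a frailty-free fit of the same
#' covariates.  All three are apparent (in-sample) errors on the supplied
#' cohort.
#'
#' @param fit_joint converged joint `jf_fit`.
#' @param fit_free converged frailty-free `jf_fit` (`theta_zero = TRUE`);
#'   omit to skip the comparator.
#' @param counting the `jf_counting` both fits refer to.
#' @param t landmark time (years).
#' @param windows vector of windows (> 0, years).
#' @return data.frame with `t`, `window`, `predictor`, `epe`,
#'   `n_at_risk`, `effective_n`.
#' @export
prediction_error_curve <- function(fit_joint, fit_free = NULL, counting,
                                   t, windows) {
  G <- censoring_survival(counting)
  kinds <- list(P1 = list(fit = fit_joint, kind = "P1"),
                P2 = list(fit = fit_joint, kind = "P2"))
  if (!is.null(fit_free))
    kinds$frailty_free <- list(fit = fit_free, kind = "free")
  out <- list()
  for (nm in names(kinds)) {
    for (w in windows) {
      pr <- predict_cohort(kinds[[nm]]$fit, counting, t, w,
                           kinds[[nm]]$kind)
      e <- expected_prediction_error(pr, counting, t, w, G)
      out[[length(out) + 1L]] <-
        data.frame(t = t, window = w, predictor = nm, epe = e$epe,
                   n_at_risk = e$n_at_risk, effective_n = e$effective_n,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
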