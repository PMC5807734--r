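#' Breast-cancer cohort codebook
#'
#' Covariate codebook used by the packaged scenarios and risk-profile
#' presets: hormone-receptor status, tumor grade, tumor size, axillary
#' nodal involvement, recent menopausal-hormone-treatment (MHT) use,
#' smoking status after diagnosis, period of diagnosis, age class at
#' diagnosis, and menopausal status.  The first level of each covariate
#' is the reference.
#'
#' @return named list of character level vectors.
#' @export
breast_cohort_codebook <- function() {
  list(receptors = c("pos_pos", "pos_neg", "neg_pos", "neg_neg"),
       grade = c("well", "moderate", "poor"),
       size = c("lt2", "ge2"),
       nodal = c("no", "yes"),
       mht = c("no", "yes"),
       smoking = c("never", "ex", "current"),
       year_dx = c("1990_1994", "1995_1999", "2000_2003", "2004_2008"),
       age_dx = c("lt50", "50_60", "60_70", "ge70"),
       menopause = c("pre", "post_no_mht", "post_mht_lt5", "post_mht_ge5"))
}

#' Published joint-model estimates for the breast-cancer cohort
#'
#' The fitted parameter vector of the multivariate joint frailty model on
#' the complete-case breast-cancer cohort: frailty variance `theta =
#' 1.01`, frailty power `alpha = 4.29`, and the hazard ratios of both
#' submodels, together with the complete-case category frequencies.
#' These define the generating law of the `"paper"` scenario preset.
#'
#' @return list with `theta`, `alpha`, `hr_recurrence`, `hr_death`
#'   (named HR vectors, names `"var=level"`), and `frequencies` (named
#'   list of per-level probabilities).
#' @export
breast_joint_estimates <- function() {
  list(
    theta = 1.01, alpha = 4.29,
    hr_recurrence = c(
      "receptors=pos_neg" = 1.40, "receptors=neg_pos" = 1.00,
      "receptors=neg_neg" = 2.14,
      "grade=moderate" = 1.61, "grade=poor" = 1.90,
      "size=ge2" = 1.64, "nodal=yes" = 1.54, "mht=yes" = 0.75,
      "smoking=ex" = 1.20, "smoking=current" = 1.55,
      "year_dx=1995_1999" = 0.90, "year_dx=2000_2003" = 0.72,
      "year_dx=2004_2008" = 0.61),
    hr_death = c(
      "receptors=pos_neg" = 2.51, "receptors=neg_pos" = 5.63,
      "receptors=neg_neg" = 9.76,
      "grade=moderate" = 3.12, "grade=poor" = 6.54,
      "size=ge2" = 4.70, "nodal=yes" = 5.23,
      "age_dx=50_60" = 1.80, "age_dx=60_70" = 4.50, "age_dx=ge70" = 9.08,
      "menopause=post_no_mht" = 1.39, "menopause=post_mht_lt5" = 0.79,
      "menopause=post_mht_ge5" = 0.35),
    frequencies = list(
      receptors = c(pos_pos = 0.617, pos_neg = 0.186, neg_pos = 0.041,
                    neg_neg = 0.156),
      grade = c(well = 0.151, moderate = 0.364, poor = 0.485),
      size = c(lt2 = 0.795, ge2 = 0.205),
      nodal = c(no = 0.700, yes = 0.300),
      mht = c(no = 0.557, yes = 0.443),
      smoking = c(never = 0.566, ex = 0.369, current = 0.065),
      year_dx = c("1990_1994" = 0.114, "1995_1999" = 0.289,
                  "2000_2003" = 0.323, "2004_2008" = 0.274),
      age_dx = c(lt50 = 0.084, "50_60" = 0.441, "60_70" = 0.380,
                 ge70 = 0.095),
      menopause = c(pre = 0.148, post_no_mht = 0.271,
                    post_mht_lt5 = 0.293, post_mht_ge5 = 0.288)))
}

#' Scenario: generating law for synthetic cohorts
#'
#' A scenario encodes the data-generating process the joint frailty model
#' assumes: a mean-one gamma frailty with variance `theta` multiplying
#' the recurrence intensity and, raised to `alpha`, the death hazard;
#' independent categorical covariates with per-submodel log hazard
#' ratios; administrative censoring at `horizon` optionally combined with
#' uniform dropout on a window; and a cap on the number of recurrences
#' per subject.
#'
#' @param n_subjects cohort size.
#' @param theta frailty variance (>= 0; 0 gives `u = 1`).
#' @param alpha frailty power on the death hazard.
#' @param baseline_R,baseline_D `jf_baseline` objects.
#' @param covariates list of elements built by [scenario_covariate()].
#' @param horizon administrative censoring horizon (years, > 0).
#' @param dropout optional `c(lo, hi)`: additional censoring uniform on
#'   the window, independent of the frailty.
#' @param cap maximum recurrences per subject (>= 1).
#' @param type_probs probabilities of the three recurrence types
#'   (locoregional, metastasis, second primary).
#' @param prep optional artifact rates exercising the preparation rules:
#'   `p_unconfirmed`, `p_type_missing` (per event), `p_mets_at_death`
#'   (per death), `n_in_situ`, `n_metastatic` (padding subjects).
#' @return an object of class `jf_scenario`.
#' @export
scenario <- function(n_subjects, theta, alpha, baseline_R, baseline_D,
                     covariates = list(), horizon, dropout = NULL,
                     cap = 10, type_probs = c(locoregional = 0.257,
                                              metastasis = 0.452,
                                              second_primary = 0.291),
                     prep = list()) {
  stopifnot(n_subjects >= 1, theta >= 0, is.finite(alpha),
            inherits(baseline_R, "jf_baseline"),
            inherits(baseline_D, "jf_baseline"),
            horizon > 0, cap >= 1,
            abs(sum(type_probs) - 1) < 1e-8)
  if (!is.null(dropout))
    stopifnot(length(dropout) == 2L, dropout[1] >= 0,
              dropout[2] > dropout[1])
  for (cv in covariates) {
    stopifnot(inherits(cv, "jf_scenario_covariate"))
    if (abs(sum(cv$probs) - 1) > 1e-8)
      stop("probabilities of covariate '", cv$name, "' must sum to 1")
  }
  prep_full <- list(p_unconfirmed = 0, p_type_missing = 0,
                    p_mets_at_death = 0, n_in_situ = 0L, n_metastatic = 0L)
  prep_full[names(prep)] <- prep
  structure(list(n_subjects = as.integer(n_subjects), theta = theta,
                 alpha = alpha, baseline_R = baseline_R,
                 baseline_D = baseline_D, covariates = covariates,
                 horizon = horizon, dropout = dropout, cap = as.integer(cap),
                 type_probs = type_probs, prep = prep_full),
            class = "jf_scenario")
}

#' @rdname scenario
#' @param name covariate name.
#' @param levels category labels, reference first.
#' @param probs sampling probabilities (sum to 1).
#' @param log_hr_recurrence,log_hr_death named log hazard ratios for the
#'   non-reference levels in the respective submodel (omit for a
#'   covariate absent from that submodel).
#' @export
scenario_covariate <- function(name, levels, probs,
                               log_hr_recurrence = NULL,
                               log_hr_death = NULL) {
  stopifnot(length(levels) == length(probs), length(levels) >= 2)
  chk <- function(lhr) {
    if (is.null(lhr)) return(NULL)
    if (is.null(names(lhr)) || !all(names(lhr) %in% levels[-1]))
      stop("log hazard ratios of '", name,
           "' must be named by non-reference levels")
    lhr[levels[-1]][!is.na(lhr[levels[-1]])]
  }
  structure(list(name = name, levels = levels, probs = probs,
                 log_hr_recurrence = chk(log_hr_recurrence),
                 log_hr_death = chk(log_hr_death)),
            class = "jf_scenario_covariate")
}

scenario_codebook <- function(scn) {
  cb <- lapply(scn$covariates, function(cv) cv$levels)
  names(cb) <- vapply(scn$covariates, function(cv) cv$name, character(1))
  cb
}

# Linear predictors per subject given sampled categories (data.frame).
scenario_eta <- function(scn, cats, which = c("recurrence", "death")) {
  which <- match.arg(which)
  field <- if (which == "recurrence") "log_hr_recurrence" else "log_hr_death"
  eta <- numeric(nrow(cats))
  for (cv in scn$covariates) {
    lhr <- cv[[field]]
    if (is.null(lhr) || !length(lhr)) next
    m <- lhr[cats[[cv$name]]]
    m[is.na(m)] <- 0
    eta <- eta + m
  }
  eta
}

#' Design specification matching a scenario
#'
#' @param scn a `jf_scenario`.
#' @return a `jf_design` whose recurrence and death covariate sets are
#'   the scenario covariates with effects in the respective submodel.
#' @export
scenario_design <- function(scn) {
  has <- function(field) vapply(scn$covariates, function(cv)
    !is.null(cv[[field]]) && length(cv[[field]]) > 0, logical(1))
  nm <- vapply(scn$covariates, function(cv) cv$name, character(1))
  make_design(scenario_codebook(scn),
              recurrent = nm[has("log_hr_recurrence")],
              death = nm[has("log_hr_death")])
}

#' Simulate a cohort from a scenario
#'
#' Per subject: draw the frailty `u` (Gamma, mean 1, variance `theta`;
#' `u = 1` if `theta = 0`) and covariate categories; draw the death time
#' by inverse transform on the cumulative death hazard scaled by
#' `u^alpha exp(eta_D)`; draw recurrence times sequentially on the
#' calendar timescale by inversion of the cumulative recurrence hazard
#' scaled by `u exp(eta_R)`, stopping at death, censoring, or the cap;
#' apply administrative and dropout censoring.  Fully reproducible given
#' the seed.
#'
#' @param scn a `jf_scenario`.
#' @param seed integer RNG seed.
#' @return a `jf_cohort`; attributes `n_capped` (subjects that hit the
#'   recurrence cap) and `seed`.
#' @export
simulate_cohort <- function(scn, seed) {
  stopifnot(inherits(scn, "jf_scenario"))
  set.seed(seed)
  n <- scn$n_subjects
  ids <- sprintf("S%05d", seq_len(n))
  cats <- data.frame(row.names = seq_len(n))
  for (cv in scn$covariates)
    cats[[cv$name]] <- sample(cv$levels, n, TRUE, cv$probs)
  u <- if (scn$theta > 0)
    pmax(stats::rgamma(n, shape = 1 / scn$theta, scale = scn$theta),
         .Machine$double.xmin)
  else rep(1, n)
  etaR <- scenario_eta(scn, cats, "recurrence")
  etaD <- scenario_eta(scn, cats, "death")
  mR <- u * exp(etaR)
  mD <- exp(scn$alpha * log(u)) * exp(etaD)
  TD <- inverse_cumulative_baseline_hazard(scn$baseline_D,
                                           stats::rexp(n) / mD)
  C <- rep(scn$horizon, n)
  if (!is.null(scn$dropout))
    C <- pmin(C, stats::runif(n, scn$dropout[1], scn$dropout[2]))
  Tt <- pmin(TD, C)
  delta <- TD <= C
  n_capped <- 0L
  ev <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- numeric(0)
    lam <- cumulative_baseline_hazard(scn$baseline_R, 0)
    repeat {
      lam <- lam + stats::rexp(1) / mR[i]
      tn <- inverse_cumulative_baseline_hazard(scn$baseline_R, lam)
      if (!is.finite(tn) || tn >= Tt[i]) break
      tt <- c(tt, tn)
      if (length(tt) >= scn$cap) { n_capped <- n_capped + 1L; break }
    }
    ev[[i]] <- tt
  }
  nev <- lengths(ev)
  events <- data.frame(
    subject_id = rep(ids, nev),
    time = if (sum(nev)) unlist(ev) else numeric(0),
    type = sample(names(scn$type_probs), sum(nev), TRUE, scn$type_probs),
    confirmed = rep(TRUE, sum(nev)), type_known = rep(TRUE, sum(nev)),
    stringsAsFactors = FALSE)
  if (scn$prep$p_unconfirmed > 0 && nrow(events))
    events$confirmed <- stats::runif(nrow(events)) >= scn$prep$p_unconfirmed
  if (scn$prep$p_type_missing > 0 && nrow(events))
    events$type_known <- stats::runif(nrow(events)) >= scn$prep$p_type_missing
  subjects <- data.frame(subject_id = ids, terminal_time = Tt,
                         terminal_status = ifelse(delta, "death", "censored"),
                         in_situ = FALSE, metastatic_dx = FALSE,
                         mets_at_death_only = FALSE, stringsAsFactors = FALSE)
  if (scn$prep$p_mets_at_death > 0 && any(delta))
    subjects$mets_at_death_only <- delta &
      stats::runif(n) < scn$prep$p_mets_at_death
  for (v in names(cats)) subjects[[v]] <- cats[[v]]
  # roster padding exercising the eligibility filter
  pad <- function(k, prefix, in_situ) {
    if (!k) return(NULL)
    p <- data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(k)),
                    terminal_time = scn$horizon,
                    terminal_status = "censored", in_situ = in_situ,
                    metastatic_dx = !in_situ, mets_at_death_only = FALSE,
                    stringsAsFactors = FALSE)
    for (cv in scn$covariates)
      p[[cv$name]] <- sample(cv$levels, k, TRUE, cv$probs)
    p
  }
  subjects <- rbind(subjects,
                    pad(scn$prep$n_in_situ, "INSITU", TRUE),
                    pad(scn$prep$n_metastatic, "METDX", FALSE))
  out <- new_cohort(subjects, events, scenario_codebook(scn))
  attr(out, "n_capped") <- n_capped
  attr(out, "seed") <- seed
  out
}

#' Calibrate Weibull baseline scales to marginal event frequencies
#'
#' Solves, by root finding on Monte-Carlo averages with common random
#' numbers, for the death and recurrence baseline scales such that the
#' simulated cohort has approximately the requested marginal fraction of
#' deaths and of subjects with at least one recurrence within follow-up.
#' Deterministic given `mc_seed`; the caller's RNG state is untouched.
#'
#' @param scn a `jf_scenario` with Weibull baselines.
#' @param target_recurrence target fraction of subjects with >= 1
#'   observed recurrence.
#' @param target_death target fraction of observed deaths.
#' @param n_mc Monte-Carlo draws used in the calibration.
#' @param mc_seed seed of the calibration draws (part of the scenario
#'   definition, not of downstream simulations).
#' @return the scenario with calibrated baseline scales.
#' @export
calibrate_baselines <- function(scn, target_recurrence = 0.18,
                                target_death = 0.095, n_mc = 4000,
                                mc_seed = 20180209) {
  stopifnot(inherits(scn, "jf_scenario"),
            inherits(scn$baseline_R, "jf_weibull"),
            inherits(scn$baseline_D, "jf_weibull"))
  draws <- with_private_seed(mc_seed, {
    cats <- data.frame(row.names = seq_len(n_mc))
    for (cv in scn$covariates)
      cats[[cv$name]] <- sample(cv$levels, n_mc, TRUE, cv$probs)
    u <- if (scn$theta > 0)
      stats::rgamma(n_mc, shape = 1 / scn$theta, scale = scn$theta)
    else rep(1, n_mc)
    C <- rep(scn$horizon, n_mc)
    if (!is.null(scn$dropout))
      C <- pmin(C, stats::runif(n_mc, scn$dropout[1], scn$dropout[2]))
    list(u = u, E = stats::rexp(n_mc),
         etaR = scenario_eta(scn, cats, "recurrence"),
         etaD = scenario_eta(scn, cats, "death"), C = C)
  })
  mD <- exp(scn$alpha * log(draws$u)) * exp(draws$etaD)
  kD <- scn$baseline_D$shape
  f_death <- function(ls) {
    TD <- exp(ls) * (draws$E / mD)^(1 / kD)
    mean(TD <= draws$C) - target_death
  }
  if (f_death(-6) < 0 || f_death(12) > 0)
    stop("death target ", target_death, " is infeasible for this scenario")
  lsD <- stats::uniroot(f_death, c(-6, 12), tol = 1e-8)$root
  TD <- exp(lsD) * (draws$E / mD)^(1 / kD)
  Tobs <- pmin(TD, draws$C)
  mR <- draws$u * exp(draws$etaR)
  kR <- scn$baseline_R$shape
  f_rec <- function(ls) {
    mean(-expm1(-mR * (Tobs / exp(ls))^kR)) - target_recurrence
  }
  if (f_rec(-6) < 0 || f_rec(12) > 0)
    stop("recurrence target ", target_recurrence,
         " is infeasible for this scenario")
  lsR <- stats::uniroot(f_rec, c(-6, 12), tol = 1e-8)$root
  scn$baseline_D <- weibull_baseline(kD, exp(lsD))
  scn$baseline_R <- weibull_baseline(kR, exp(lsR))
  attr(scn, "calibration") <- list(target_recurrence = target_recurrence,
                                   target_death = target_death,
                                   n_mc = n_mc, mc_seed = mc_seed)
  scn
}

#' Packaged scenario presets
#'
#' `"paper"`: the published joint-model parameter vector (`theta = 1.01`,
#' `alpha = 4.29`, both submodels' hazard ratios, complete-case covariate
#' frequencies), Weibull (exponential-shape) baselines calibrated so that
#' about 18 percent of subjects have at least one recurrence and about
#' 9.5 percent die within follow-up, administrative censoring at 18
#' years combined with uniform dropout on (0.5, 18) years.
#' `"null"`: no frailty (`theta = 0`), a single binary covariate.
#' `"smoke"`: 100 subjects, one covariate, preparation artifacts
#' (unconfirmed events, missing types, metastases reported at death,
#' roster padding) switched on for end-to-end pipeline exercise.
#'
#' @param name preset name.
#' @param n_subjects cohort size override.
#' @param calibrate run [calibrate_baselines()] for the `"paper"` preset.
#' @return a `jf_scenario`.
#' @export
scenario_preset <- function(name = c("paper", "null", "smoke"),
                            n_subjects = NULL, calibrate = TRUE) {
  name <- match.arg(name)
  if (name == "paper") {
    est <- breast_joint_estimates()
    fr <- est$frequencies
    covs <- lapply(names(fr), function(v) {
      lv <- names(fr[[v]])
      pick <- function(hr) {
        nm <- paste0(v, "=", lv[-1])
        hit <- nm %in% names(hr)
        if (!any(hit)) return(NULL)
        stats::setNames(log(hr[nm[hit]]), lv[-1][hit])
      }
      scenario_covariate(v, lv, unname(fr[[v]]),
                         log_hr_recurrence = pick(est$hr_recurrence),
                         log_hr_death = pick(est$hr_death))
    })
    scn <- scenario(n_subjects %||% 4926, est$theta, est$alpha,
                    weibull_baseline(1, 30), weibull_baseline(1, 60),
                    covariates = covs, horizon = 18,
                    dropout = c(0.5, 18), cap = 10)
    if (calibrate) scn <- calibrate_baselines(scn)
    scn
  } else if (name == "null") {
    scenario(n_subjects %||% 2000, theta = 0, alpha = 1,
             weibull_baseline(1, 8), weibull_baseline(1, 40),
             covariates = list(scenario_covariate(
               "group", c("a", "b"), c(0.5, 0.5),
               log_hr_recurrence = c(b = log(2)),
               log_hr_death = c(b = log(1.5)))),
             horizon = 10)
  } else {
    scenario(n_subjects %||% 100, theta = 1, alpha = 1.5,
             weibull_baseline(1, 6), weibull_baseline(1, 25),
             covariates = list(scenario_covariate(
               "group", c("a", "b"), c(0.5, 0.5),
               log_hr_recurrence = c(b = log(2)),
               log_hr_death = c(b = log(2)))),
             horizon = 10, dropout = c(0.5, 12), cap = 10,
             prep = list(p_unconfirmed = 0.05, p_type_missing = 0.02,
                         p_mets_at_death = 0.1, n_in_situ = 5L,
                         n_metastatic = 2L))
  }
}

#' Scenario from fitted or printed estimates
#'
#' Builds a scenario whose generating parameters equal the supplied
#' estimates.  `x` may be a `jf_fit` or a list with `theta`, `alpha`,
#' `beta_R`, `beta_D` (log hazard ratios named `"var=level"`),
#' `baseline_R`, `baseline_D`.  The template supplies everything the
#' estimates do not determine: covariate sampling frequencies, censoring,
#' cap and cohort size.  If calibration `targets` are given, baseline
#' scales are re-solved to match the requested marginal frequencies.
#'
#' @param x a `jf_fit` or a list of estimates.
#' @param template a `jf_scenario` with the same covariate structure.
#' @param targets optional `list(recurrence =, death =)` marginal
#'   frequencies for [calibrate_baselines()].
#' @return a `jf_scenario`.
#' @export
scenario_from_fitted <- function(x, template, targets = NULL) {
  stopifnot(inherits(template, "jf_scenario"))
  if (inherits(x, "jf_fit")) {
    est <- list(theta = x$params$theta, alpha = x$params$alpha,
                beta_R = x$params$beta_R, beta_D = x$params$beta_D,
                baseline_R = x$params$baseline_R,
                baseline_D = x$params$baseline_D)
  } else est <- x
  need <- c("theta", "alpha", "beta_R", "beta_D", "baseline_R", "baseline_D")
  miss <- setdiff(need, names(est))
  if (length(miss))
    stop("incomplete parameter set: missing ", paste(miss, collapse = ", "))
  scn <- template
  scn$theta <- est$theta
  scn$alpha <- est$alpha
  scn$baseline_R <- est$baseline_R
  scn$baseline_D <- est$baseline_D
  scn$covariates <- lapply(template$covariates, function(cv) {
    pick <- function(beta) {
      nm <- paste0(cv$name, "=", cv$levels[-1])
      hit <- nm %in% names(beta)
      if (!any(hit)) return(NULL)
      stats::setNames(beta[nm[hit]], cv$levels[-1][hit])
    }
    scenario_covariate(cv$name, cv$levels, cv$probs,
                       log_hr_recurrence = pick(est$beta_R),
                       log_hr_death = pick(est$beta_D))
  })
  if (!is.null(targets))
    scn <- calibrate_baselines(scn,
                               target_recurrence = targets$recurrence,
                               target_death = targets$death)
  scn
}

#' @export
print.jf_scenario <- function(x, ...) {
  cat(sprintf("jf_scenario: n = %d, theta = %.3g, alpha = %.3g, horizon = %g y\n",
              x$n_subjects, x$theta, x$alpha, x$horizon))
  cat(sprintf("  %d covariates; cap %d recurrences; dropout %s\n",
              length(x$covariates), x$cap,
              if (is.null(x$dropout)) "none"
              else paste0("U(", x$dropout[1], ", ", x$dropout[2], ")")))
  print(x$baseline_R); print(x$baseline_D)
  invisible(x)
}
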