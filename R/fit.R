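#' Fit the joint frailty model by maximum marginal likelihood
#'
#' Maximizes the quadrature marginal likelihood over
#' `(log theta, alpha, beta_R, beta_D, log baseline parameters)` with
#' `L-BFGS-B`.  Starting values come from a Weibull AFT fit of the death
#' submodel (`survival::survreg`) and a Poisson count regression of the
#' recurrence submodel, both frailty-free.  With `theta_zero = TRUE` the
#' frailty is fixed at `u = 1` (no `theta`, no `alpha`): the two
#' submodels decouple and the fit is the frailty-free comparator.
#'
#' @param counting a `jf_counting` from [build_counting_process()].
#' @param baseline `"weibull"` (default) or `"piecewise"`.
#' @param cuts interior cut points for the piecewise baseline (shared by
#'   both submodels).
#' @param theta_zero fit the frailty-free limit instead of the joint
#'   model.
#' @param nodes quadrature nodes for the frailty integral.
#' @param init optional named list overriding starting values
#'   (`theta`, `alpha`, `beta_R`, `beta_D`, `baseline_R`, `baseline_D`).
#' @param control list with `maxit` (default 400) and `factr` (default
#'   1e7, the `optim` L-BFGS-B tolerance).
#' @return an object of class `jf_fit`: fitted `params`, estimation-scale
#'   parameter vector `par` and covariance `vcov`, `loglik`,
#'   `convergence` diagnostics and data counts.
#' @export
fit_joint_model <- function(counting, baseline = c("weibull", "piecewise"),
                            cuts = NULL, theta_zero = FALSE, nodes = 32,
                            init = NULL, control = list()) {
  stopifnot(inherits(counting, "jf_counting"))
  baseline <- match.arg(baseline)
  dat <- counting_dat(counting)
  n_deaths <- sum(dat$delta)
  n_rec <- sum(dat$J)
  if (n_deaths == 0L)
    stop("no deaths in the data: the death submodel (and the frailty ",
         "power alpha) is unidentifiable")
  if (n_rec == 0L)
    stop("no recurrent events in the data: the recurrence submodel (and ",
         "the frailty variance theta) is unidentifiable")
  check_rank(dat$XR, "recurrence")
  check_rank(dat$XD, "death")
  maxit <- control$maxit %||% 400L
  factr <- control$factr %||% 1e7

  if (baseline == "weibull") {
    tplR <- tplD <- weibull_baseline(1, 1)
  } else {
    if (is.null(cuts))
      cuts <- stats::quantile(dat$T, c(0.25, 0.5, 0.75), names = FALSE)
    tplR <- tplD <- piecewise_baseline(cuts, rep(0.1, length(cuts) + 1))
  }
  pR <- ncol(dat$XR); pD <- ncol(dat$XD)
  start <- starting_values(dat, tplR, tplD, theta_zero, init)
  spec <- list(theta_zero = theta_zero, pR = pR, pD = pD,
               tplR = tplR, tplD = tplD, nodes = nodes,
               names_R = colnames(dat$XR), names_D = colnames(dat$XD))

  cache <- new.env(parent = emptyenv())
  evalb <- function(par) {
    if (is.null(cache$par) || !identical(par, cache$par)) {
      res <- joint_nll_grad(par, dat, spec, nodes)
      if (!theta_zero && res$value < 1e10) {
        # the posterior moments behind the analytic log-theta and alpha
        # scores converge more slowly than the value itself, which
        # matters on the flat (theta, alpha) ridge: use accurate central
        # differences of the value for those two components
        h <- 1e-5
        for (k in 1:2) {
          ep <- par; ep[k] <- ep[k] + h
          em <- par; em[k] <- em[k] - h
          res$grad[k] <- (joint_nll_grad(ep, dat, spec, nodes)$value -
                            joint_nll_grad(em, dat, spec, nodes)$value) /
            (2 * h)
        }
      }
      cache$res <- res
      cache$par <- par
    }
    cache$res
  }
  fn <- function(par) evalb(par)$value
  gr <- function(par) evalb(par)$grad
  bounds <- par_bounds(spec)
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = bounds$lower, upper = bounds$upper,
                      control = list(maxit = maxit, factr = factr))
  # the (theta, alpha) profile can be a long flat ridge; restarting the
  # limited-memory optimizer until the objective stops improving guards
  # against premature termination
  for (restart in 1:4) {
    opt2 <- stats::optim(opt$par, fn, gr, method = "L-BFGS-B",
                         lower = bounds$lower, upper = bounds$upper,
                         control = list(maxit = maxit, factr = factr))
    improved <- opt$value - opt2$value
    if (opt2$value <= opt$value) opt <- opt2
    if (improved < 1e-4) break
  }
  H <- tryCatch(stats::optimHess(opt$par, fn, gr), error = function(e) NULL)
  vc <- NULL
  cov_ok <- FALSE
  if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc)) {
      vc <- (vc + t(vc)) / 2
      cov_ok <- all(diag(vc) >= 0)
      dimnames(vc) <- list(names(start), names(start))
    }
  }
  grad <- gr(opt$par)
  status <- if (opt$convergence == 0) "converged" else "not_converged"
  params <- unpack_par(opt$par, spec)
  params <- joint_frailty_params(
    params$theta, params$alpha,
    stats::setNames(params$beta_R, spec$names_R),
    stats::setNames(params$beta_D, spec$names_D),
    params$baseline_R, params$baseline_D)
  structure(list(params = params, par = opt$par, vcov = vc,
                 covariance_ok = cov_ok,
                 loglik = -opt$value, spec = spec,
                 design = counting$design,
                 convergence = list(status = status,
                                    iterations = opt$counts[["function"]],
                                    gradient_norm = max(abs(grad)),
                                    message = opt$message),
                 counts = list(subjects = dat$n, recurrences = n_rec,
                               deaths = n_deaths),
                 max_time = max(dat$T), nodes = nodes,
                 theta_zero = theta_zero),
            class = "jf_fit")
}

check_rank <- function(X, label) {
  if (!ncol(X)) return(invisible())
  const <- apply(X, 2, function(c) max(c) == min(c))
  if (any(const))
    stop("rank-deficient ", label, " design: constant column(s) ",
         paste(colnames(X)[const], collapse = ", "))
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("rank-deficient ", label, " design matrix")
  invisible()
}

numeric_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# estimation-scale parameter vector layout:
# [log theta, alpha]? + beta_R + beta_D + log-baseline_R + log-baseline_D
unpack_par <- function(par, spec) {
  i <- 0L
  if (!spec$theta_zero) {
    theta <- unname(exp(par[1])); alpha <- unname(par[2]); i <- 2L
  } else {
    theta <- 0; alpha <- 1
  }
  beta_R <- par[i + seq_len(spec$pR)]; i <- i + spec$pR
  beta_D <- par[i + seq_len(spec$pD)]; i <- i + spec$pD
  nbR <- n_baseline_par(spec$tplR)
  bR <- unpack_baseline(spec$tplR, par[i + seq_len(nbR)]); i <- i + nbR
  nbD <- n_baseline_par(spec$tplD)
  bD <- unpack_baseline(spec$tplD, par[i + seq_len(nbD)])
  list(theta = theta, alpha = alpha, beta_R = beta_R, beta_D = beta_D,
       baseline_R = bR, baseline_D = bD)
}

par_names <- function(spec) {
  c(if (!spec$theta_zero) c("log_theta", "alpha"),
    if (spec$pR) paste0("R:", spec$names_R),
    if (spec$pD) paste0("D:", spec$names_D),
    baseline_par_names(spec$tplR, "R:"),
    baseline_par_names(spec$tplD, "D:"))
}

par_bounds <- function(spec) {
  nbR <- n_baseline_par(spec$tplR); nbD <- n_baseline_par(spec$tplD)
  bl_lo <- function(tpl, nb) if (inherits(tpl, "jf_weibull")) c(-3, -6)
                             else rep(-16, nb)
  bl_hi <- function(tpl, nb) if (inherits(tpl, "jf_weibull")) c(3, 16)
                             else rep(5, nb)
  lower <- c(if (!spec$theta_zero) c(-5, -10),
             rep(-8, spec$pR + spec$pD), bl_lo(spec$tplR, nbR),
             bl_lo(spec$tplD, nbD))
  upper <- c(if (!spec$theta_zero) c(3, 10),
             rep(8, spec$pR + spec$pD), bl_hi(spec$tplR, nbR),
             bl_hi(spec$tplD, nbD))
  list(lower = lower, upper = upper)
}

starting_values <- function(dat, tplR, tplD, theta_zero, init = NULL) {
  pR <- ncol(dat$XR); pD <- ncol(dat$XD)
  # death submodel: Weibull AFT -> PH parameterization
  gamma0 <- numeric(pD); kD <- 1
  scaleD <- max(dat$T) / max(sum(dat$delta), 1)
  sr <- tryCatch({
    df <- data.frame(T = dat$T, d = dat$delta)
    X <- dat$XD
    fit <- if (pD) suppressWarnings(survival::survreg(
             survival::Surv(T, d) ~ X, data = df, dist = "weibull"))
           else suppressWarnings(survival::survreg(
             survival::Surv(T, d) ~ 1, data = df, dist = "weibull"))
    co <- stats::coef(fit)
    list(k = 1 / fit$scale, scale = exp(co[1]),
         gamma = if (pD) -co[-1] / fit$scale else numeric(0))
  }, error = function(e) NULL)
  if (!is.null(sr) && all(is.finite(c(sr$k, sr$scale, sr$gamma)))) {
    kD <- min(max(sr$k, 0.2), 5); scaleD <- min(max(sr$scale, 0.01), 1e6)
    gamma0 <- pmin(pmax(sr$gamma, -5), 5)
  }
  # recurrence submodel: Poisson counts with log-time offset
  beta0 <- numeric(pR)
  rate0 <- sum(dat$J) / sum(dat$T)
  gl <- tryCatch({
    df <- data.frame(J = dat$J, off = log(dat$T))
    X <- dat$XR
    fit <- if (pR) suppressWarnings(stats::glm(
             J ~ X + offset(off), family = stats::poisson, data = df))
           else suppressWarnings(stats::glm(
             J ~ offset(off), family = stats::poisson, data = df))
    co <- stats::coef(fit)
    list(rate = exp(co[1]), beta = if (pR) co[-1] else numeric(0))
  }, error = function(e) NULL)
  if (!is.null(gl) && all(is.finite(c(gl$rate, gl$beta)))) {
    rate0 <- min(max(gl$rate, 1e-6), 100)
    beta0 <- pmin(pmax(gl$beta, -5), 5)
  }
  bR0 <- if (inherits(tplR, "jf_weibull")) weibull_baseline(1, 1 / rate0)
         else piecewise_baseline(tplR$cuts, rep(rate0, length(tplR$rates)))
  dratio <- max(sum(dat$delta), 1) / sum(dat$T)
  bD0 <- if (inherits(tplD, "jf_weibull")) weibull_baseline(kD, scaleD)
         else piecewise_baseline(tplD$cuts, rep(dratio, length(tplD$rates)))
  theta0 <- 0.5; alpha0 <- 1
  if (!is.null(init)) {
    theta0 <- init$theta %||% theta0
    alpha0 <- init$alpha %||% alpha0
    if (!is.null(init$beta_R)) beta0 <- init$beta_R
    if (!is.null(init$beta_D)) gamma0 <- init$beta_D
    if (!is.null(init$baseline_R)) bR0 <- init$baseline_R
    if (!is.null(init$baseline_D)) bD0 <- init$baseline_D
  }
  start <- c(if (!theta_zero) c(log(theta0), alpha0),
             beta0, gamma0, pack_baseline(bR0), pack_baseline(bD0))
  names(start) <- par_names(list(theta_zero = theta_zero, pR = pR, pD = pD,
                                 tplR = tplR, tplD = tplD,
                                 names_R = colnames(dat$XR),
                                 names_D = colnames(dat$XD)))
  start
}

#' Hazard-ratio table with Wald inference
#'
#' Exponentiated coefficients with 95 percent Wald confidence intervals
#' and two-sided p-values for both submodels, plus natural-scale
#' estimates, delta-method standard errors, and Wald tests against zero
#' for the frailty variance and power.  The Wald test for `theta` is
#' reported without a boundary correction (its null lies on the edge of
#' the parameter space), mirroring common reporting practice.
#'
#' @param fit a converged `jf_fit` with an available covariance.
#' @return an object of class `jf_wald` with elements `coefficients`
#'   (data.frame), `theta`, `alpha`, `baseline` (data.frame).
#' @export
wald_summary <- function(fit) {
  stopifnot(inherits(fit, "jf_fit"))
  if (fit$convergence$status != "converged")
    stop("model did not converge; no inference available")
  if (is.null(fit$vcov))
    stop("covariance matrix unavailable; no inference available")
  se <- sqrt(pmax(diag(fit$vcov), 0))
  nm <- names(fit$par)
  co_idx <- grep("^[RD]:.*=", nm)
  coefs <- NULL
  if (length(co_idx)) {
    est <- fit$par[co_idx]
    s <- se[co_idx]
    z <- est / s
    coefs <- data.frame(
      term = sub("^[RD]:", "", nm[co_idx]),
      submodel = ifelse(grepl("^R:", nm[co_idx]), "recurrence", "death"),
      estimate = est, se = s, hr = exp(est),
      ci_low = exp(est - 1.96 * s), ci_high = exp(est + 1.96 * s),
      p = 2 * stats::pnorm(-abs(z)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  th <- al <- NULL
  if (!fit$theta_zero) {
    theta <- exp(fit$par["log_theta"])
    se_th <- theta * se[match("log_theta", nm)]     # delta method
    al_se <- se[match("alpha", nm)]
    th <- list(estimate = unname(theta), se = unname(se_th),
               p = unname(2 * stats::pnorm(-abs(theta / se_th))))
    al <- list(estimate = unname(fit$par["alpha"]), se = unname(al_se),
               p = unname(2 * stats::pnorm(-abs(fit$par["alpha"] / al_se))))
  }
  bl_idx <- setdiff(seq_along(nm), c(co_idx,
                                     match(c("log_theta", "alpha"), nm)))
  bl_idx <- bl_idx[!is.na(bl_idx)]
  baseline <- data.frame(term = nm[bl_idx],
                         estimate = exp(fit$par[bl_idx]),
                         se = exp(fit$par[bl_idx]) * se[bl_idx],
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = coefs, theta = th, alpha = al,
                 baseline = baseline, counts = fit$counts),
            class = "jf_wald")
}

#' @export
print.jf_wald <- function(x, digits = 3, ...) {
  cat(sprintf("Joint model estimation (N = %d, %d recurrent events, %d deaths)\n\n",
              x$counts$subjects, x$counts$recurrences, x$counts$deaths))
  if (!is.null(x$coefficients)) {
    df <- x$coefficients
    df$estimate <- NULL
    print(format(df, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$theta))
    cat(sprintf("\ntheta %.3g (se = %.3g), p = %.3g\nalpha %.3g (se = %.3g), p = %.3g\n",
                x$theta$estimate, x$theta$se, x$theta$p,
                x$alpha$estimate, x$alpha$se, x$alpha$p))
  invisible(x)
}

#' @export
print.jf_fit <- function(x, ...) {
  cat(sprintf("Joint frailty model fit (%s)\n", x$convergence$status))
  cat(sprintf("  subjects %d, recurrences %d, deaths %d\n",
              x$counts$subjects, x$counts$recurrences, x$counts$deaths))
  cat(sprintf("  log-likelihood %.3f\n", x$loglik))
  if (!x$theta_zero)
    cat(sprintf("  theta %.3f, alpha %.3f\n",
                x$params$theta, x$params$alpha))
  else cat("  frailty-free fit (u = 1)\n")
  invisible(x)
}

# ---- serialization --------------------------------------------------------

#' Serialize a fitted model to JSON and back
#'
#' Stores the estimation-scale parameter vector, covariance, design
#' metadata and convergence diagnostics so the predict and validate
#' stages can run from a file.
#'
#' @param fit a `jf_fit`.
#' @param path output path.
#' @export
write_fitted_model <- function(fit, path) {
  stopifnot(inherits(fit, "jf_fit"))
  tpl_ser <- function(tpl) {
    if (inherits(tpl, "jf_weibull")) list(family = "weibull")
    else list(family = "piecewise_constant", cuts = tpl$cuts)
  }
  obj <- list(package = "jfrail",
              version = as.character(utils::packageVersion("jfrail")),
              par = as.list(fit$par), vcov = fit$vcov,
              covariance_ok = fit$covariance_ok,
              loglik = fit$loglik,
              theta_zero = fit$theta_zero, nodes = fit$nodes,
              max_time = fit$max_time,
              convergence = fit$convergence,
              counts = fit$counts,
              spec = list(pR = fit$spec$pR, pD = fit$spec$pD,
                          names_R = fit$spec$names_R,
                          names_D = fit$spec$names_D,
                          tplR = tpl_ser(fit$spec$tplR),
                          tplD = tpl_ser(fit$spec$tplD)),
              design = list(recurrent = fit$design$recurrent,
                            death = fit$design$death,
                            codebook = fit$design$codebook))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fitted_model
#' @export
read_fitted_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tpl_de <- function(x) {
    if (x$family == "weibull") weibull_baseline(1, 1)
    else piecewise_baseline(x$cuts, rep(0.1, length(x$cuts) + 1))
  }
  spec <- list(theta_zero = obj$theta_zero, pR = obj$spec$pR,
               pD = obj$spec$pD, tplR = tpl_de(obj$spec$tplR),
               tplD = tpl_de(obj$spec$tplD), nodes = obj$nodes,
               names_R = obj$spec$names_R, names_D = obj$spec$names_D)
  par <- unlist(obj$par)
  p <- unpack_par(par, spec)
  params <- joint_frailty_params(
    p$theta, p$alpha, stats::setNames(p$beta_R, spec$names_R),
    stats::setNames(p$beta_D, spec$names_D), p$baseline_R, p$baseline_D)
  vc <- obj$vcov
  if (!is.null(vc)) {
    vc <- as.matrix(vc)
    dimnames(vc) <- list(names(par), names(par))
  }
  design <- make_design(obj$design$codebook, obj$design$recurrent,
                        obj$design$death)
  structure(list(params = params, par = par, vcov = vc,
                 covariance_ok = isTRUE(obj$covariance_ok),
                 loglik = obj$loglik, spec = spec, design = design,
                 convergence = obj$convergence, counts = obj$counts,
                 max_time = obj$max_time, nodes = obj$nodes,
                 theta_zero = obj$theta_zero),
            class = "jf_fit")
}
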