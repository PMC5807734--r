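test_that("gamma frailty density matches the closed form and normalizes", {
  expect_equal(gamma_frailty_density(1, 1), exp(-1), tolerance = 1e-12)
  # independent evaluation of the gamma formula: shape 4, scale 0.25
  u <- 2; th <- 0.25
  expect_equal(gamma_frailty_density(u, th),
               u^(1 / th - 1) * exp(-u / th) /
                 (gamma(1 / th) * th^(1 / th)),
               tolerance = 1e-12)
  # mean-one identity by numerical integration
  m <- stats::integrate(function(u) u * gamma_frailty_density(u, 0.5),
                        0, Inf, rel.tol = 1e-10)$value
  expect_equal(m, 1, tolerance = 1e-6)
  expect_error(gamma_frailty_density(1, 0), "theta > 0")
})

test_that("frailty quadrature integrates the density to one across theta", {
  for (th in c(0.01, 0.1, 0.5, 1, 2, 5)) {
    r <- frailty_quadrature(th, 32)
    expect_equal(sum(exp(r$logw)), 1, tolerance = 1e-8)
    expect_equal(sum(exp(r$logw) * r$u), 1, tolerance = 1e-8)
    expect_equal(sum(exp(r$logw) * r$u^2) - 1, th, tolerance = 1e-7)
    expect_true(all(r$u > 0))
  }
})

test_that("Golub-Welsch Laguerre rule agrees with an independent builder", {
  for (a in c(0, 0.5, 3)) {
    mine <- gauss_laguerre(16, a)
    ref <- pracma::gaussLaguerre(16, a)
    expect_equal(mine$nodes, ref$x, tolerance = 1e-10)
    expect_equal(exp(mine$logw) * gamma(a + 1), ref$w, tolerance = 1e-9)
  }
})

test_that("cumulative baseline hazards match closed forms and invariants", {
  expect_equal(cumulative_baseline_hazard(weibull_baseline(1, 10), 5), 0.5)
  expect_equal(cumulative_baseline_hazard(weibull_baseline(2, 5), 5), 1.0)
  pw <- piecewise_baseline(2, c(0.1, 0.3))
  expect_equal(cumulative_baseline_hazard(pw, 4), 0.8)
  expect_equal(cumulative_baseline_hazard(pw, 0), 0)
  grid <- seq(0, 20, by = 0.1)
  for (spec in list(weibull_baseline(0.8, 7), pw,
                    piecewise_baseline(c(1, 4), c(0.2, 0, 0.5)))) {
    L <- cumulative_baseline_hazard(spec, grid)
    expect_true(all(diff(L) >= 0))
    expect_equal(L[1], 0)
    expect_true(all(baseline_hazard(spec, grid[-1]) >= 0))
  }
  expect_error(cumulative_baseline_hazard(pw, -1), "negative time")
})

test_that("cumulative hazard inversion round-trips, including flat pieces", {
  wb <- weibull_baseline(1.7, 6)
  y <- c(0.01, 0.4, 2, 9)
  expect_equal(cumulative_baseline_hazard(
    wb, jfrail:::inverse_cumulative_baseline_hazard(wb, y)), y,
    tolerance = 1e-10)
  pw <- piecewise_baseline(c(1, 4), c(0.2, 0, 0.5))
  t <- jfrail:::inverse_cumulative_baseline_hazard(pw, c(0.1, 0.2, 0.3))
  expect_equal(t, c(0.5, 4, 4.2))  # the zero-rate gap is jumped over
  none <- piecewise_baseline(numeric(0), 0)
  expect_equal(jfrail:::inverse_cumulative_baseline_hazard(none, 0.5), Inf)
})

test_that("marginal log-likelihood matches closed-form limits", {
  bR <- weibull_baseline(1, 5)    # constant hazard 0.2
  bD <- weibull_baseline(1, 10)   # constant hazard 0.1
  s <- list(J = 0L, delta = 1L, T = 1, event_times = numeric(0),
            x_R = numeric(0), x_D = numeric(0))
  # theta = 0: frailty-free product likelihood
  p0 <- joint_frailty_params(0, 1, numeric(0), numeric(0), bR, bD)
  expect_equal(subject_marginal_loglik(p0, s), log(0.1) - 0.3,
               tolerance = 1e-10)
  # alpha = 1, theta = 1: exponential-frailty closed form
  p1 <- joint_frailty_params(1, 1, numeric(0), numeric(0), bR, bD)
  expect_equal(subject_marginal_loglik(p1, s), log(0.1 / 1.3^2),
               tolerance = 1e-8)
  expect_equal(subject_marginal_loglik(p1, s, method = "fixed"),
               log(0.1 / 1.3^2), tolerance = 1e-8)
})

test_that("quadrature marginal likelihood matches brute-force integration", {
  set.seed(42)
  worst_adaptive <- 0
  worst_fixed <- 0
  for (i in 1:60) {
    cs <- random_subject_case()
    b <- oracle_subject_loglik(cs$params, cs$subject)
    a <- subject_marginal_loglik(cs$params, cs$subject)
    f <- subject_marginal_loglik(cs$params, cs$subject, method = "fixed")
    worst_adaptive <- max(worst_adaptive, abs(a - b) / abs(b))
    worst_fixed <- max(worst_fixed, abs(f - b) / abs(b))
  }
  expect_lt(worst_adaptive, 1e-6)
  # the optimizer's fixed rule is a documented approximation
  expect_lt(worst_fixed, 5e-4)
})

test_that("spec example at the published parameter values hits the oracle", {
  pp <- joint_frailty_params(1.01, 4.29, 0.5, 0.8,
                             weibull_baseline(1, 8),
                             weibull_baseline(1, 30))
  s <- list(J = 2L, delta = 1L, T = 6, event_times = c(1.5, 4),
            x_R = 1, x_D = 1)
  expect_equal(subject_marginal_loglik(pp, s),
               oracle_subject_loglik(pp, s), tolerance = 1e-6)
})

test_that("total log-likelihood is invariant to subject permutation", {
  co <- simulate_cohort(toy_scenario(n = 80), 9)
  des <- make_design(co$codebook, "group", "group")
  cp <- build_counting_process(co, des)
  pp <- joint_frailty_params(0.8, 1.3, c("group=b" = 0.7),
                             c("group=b" = 0.7),
                             weibull_baseline(1, 6),
                             weibull_baseline(1, 30))
  ll1 <- joint_loglik(pp, cp)
  perm <- sample(nrow(co$subjects))
  co2 <- co
  co2$subjects <- co$subjects[perm, ]
  cp2 <- build_counting_process(co2, des)
  expect_lt(abs(joint_loglik(pp, cp2) - ll1), 1e-10)
})

test_that("theta = 0 marginal equals the frailty-free product exactly", {
  co <- simulate_cohort(toy_scenario(n = 50, theta = 0, alpha = 1), 3)
  des <- make_design(co$codebook, "group", "group")
  cp <- build_counting_process(co, des)
  bR <- weibull_baseline(1.2, 7)
  bD <- weibull_baseline(0.9, 35)
  p0 <- joint_frailty_params(0, 1, c("group=b" = 0.5), c("group=b" = 0.4),
                             bR, bD)
  dat <- jfrail:::counting_dat(cp)
  etaR <- drop(dat$XR %*% 0.5)
  etaD <- drop(dat$XD %*% 0.4)
  manual <- sum(
    (dat$J > 0) * 0 +
      vapply(seq_len(dat$n), function(i) {
        ev <- dat$ev_t[dat$ev_i == i]
        (if (length(ev)) sum(log(baseline_hazard(bR, ev))) else 0) +
          dat$J[i] * etaR[i] +
          dat$delta[i] * (log(baseline_hazard(bD, dat$T[i])) + etaD[i]) -
          cumulative_baseline_hazard(bR, dat$T[i]) * exp(etaR[i]) -
          cumulative_baseline_hazard(bD, dat$T[i]) * exp(etaD[i])
      }, numeric(1)))
  expect_equal(joint_loglik(p0, cp), manual, tolerance = 1e-12)
})
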