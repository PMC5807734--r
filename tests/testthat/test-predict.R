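# A converged fit on a moderate cohort, shared across prediction tests.
fit_once <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      scn <- toy_scenario(n = 500, theta = 1, alpha = 2)
      co <- simulate_cohort(scn, 61)
      cp <- build_counting_process(co, scenario_design(scn))
      val <<- fit_joint_model(cp, nodes = 32)
    }
    val
  }
})

test_that("risk-profile presets carry the published covariate categories", {
  lo <- risk_profile("low")
  hi <- risk_profile("high")
  me <- risk_profile("medium")
  expect_equal(unname(lo["receptors"]), "pos_pos")
  expect_equal(unname(me["receptors"]), "pos_neg")
  expect_equal(unname(me["menopause"]), "pre")
  expect_equal(unname(hi["receptors"]), "neg_neg")
  expect_equal(unname(hi["age_dx"]), "ge70")
  expect_equal(unname(lo["year_dx"]), "2004_2008")
  expect_error(risk_profile(list(receptors = "nope")), "not a level")
  expect_error(risk_profile(list("pos_pos")), "named")
})

test_that("window probabilities are bounded, vanish at w = 0 and grow with w", {
  fit <- fit_once()
  p0 <- predict_p1(fit, list(group = "b"), t = 5, window = 0, events = 1)
  expect_equal(p0$probability, 0)
  ws <- c(0.5, 1, 2, 4, 7)
  p <- predict_p1(fit, list(group = "b"), t = 5, window = ws, events = 1)
  expect_true(all(p$probability >= 0 & p$probability <= 1))
  expect_true(all(diff(p$probability) >= 0))
  # long horizons approach certainty for a proper death distribution
  plarge <- suppressWarnings(predict_p1(fit, list(group = "b"), t = 2,
                                        window = 4000, events = 1))
  expect_gt(plarge$probability, 0.99)
})

test_that("theta -> 0 reduces both P1 and P2 to the frailty-free closed form", {
  bD <- weibull_baseline(1, 10)   # Lambda_D(t) = 0.1 t
  pars <- joint_frailty_params(0, 1, numeric(0), numeric(0),
                               weibull_baseline(1, 5), bD)
  p1 <- jfrail:::predict_prob_core(pars, numeric(0), numeric(0),
                                   t = 5, w = 5, J = 2, kind = "P1")
  p2 <- jfrail:::predict_prob_core(pars, numeric(0), numeric(0),
                                   t = 5, w = 5, J = 0, kind = "P2")
  expect_equal(p1, 1 - exp(-0.5), tolerance = 1e-8)
  expect_equal(p2, 1 - exp(-0.5), tolerance = 1e-8)
})

test_that("predictions agree with brute-force integration and order in J", {
  pars <- joint_frailty_params(
    1.01, 4.29, c(x = 0.5), c(x = 0.9),
    weibull_baseline(1, 8), weibull_baseline(1, 60))
  probs <- vapply(0:3, function(J) jfrail:::predict_prob_core(
    pars, 1, 1, t = 5, w = 5, J = J, kind = "P1"), numeric(1))
  # strictly increasing in the number of recurrences (alpha > 0)
  expect_true(all(diff(probs) > 0))
  for (J in 0:3)
    expect_equal(probs[J + 1],
                 oracle_predict(pars, 1, 1, 5, 5, J, "P1"),
                 tolerance = 1e-6)
  p2 <- jfrail:::predict_prob_core(pars, 1, 1, t = 5, w = 5, J = 0,
                                   kind = "P2")
  expect_equal(p2, oracle_predict(pars, 1, 1, 5, 5, 0, "P2"),
               tolerance = 1e-6)
  # P1 with no recurrences <= marginal P2 <= P1 with a long history
  expect_lt(probs[1], p2)
  expect_gt(probs[4], p2)

  # randomized requests against the oracle
  set.seed(7)
  for (i in 1:12) {
    th <- runif(1, 0.2, 1.5); al <- runif(1, 0.3, 4)
    pp <- joint_frailty_params(th, al, c(x = rnorm(1, 0, 0.4)),
                               c(x = rnorm(1, 0, 0.4)),
                               weibull_baseline(runif(1, 0.8, 1.5), 8),
                               weibull_baseline(runif(1, 0.8, 1.5), 50))
    t <- runif(1, 1, 8); w <- runif(1, 0.5, 6); J <- sample(0:3, 1)
    kind <- sample(c("P1", "P2"), 1)
    x <- rbinom(1, 1, 0.5)
    expect_equal(jfrail:::predict_prob_core(pp, x, x, t, w, J, kind),
                 oracle_predict(pp, x, x, t, w, if (kind == "P1") J else 0,
                                kind),
                 tolerance = 1e-6)
  }
})

test_that("P2 ignores the history and P1 exceeds it after recurrences", {
  fit <- fit_once()
  p2a <- predict_p2(fit, list(group = "b"), t = 5, window = 5)
  p1 <- predict_p1(fit, list(group = "b"), t = 5, window = 5, events = 2)
  expect_gt(p1$probability, p2a$probability)
  # recurrence times are validated but do not move the estimate
  p1b <- predict_p1(fit, list(group = "b"), t = 5, window = 5, events = 2,
                    recurrence_times = c(1.2, 3.4))
  expect_equal(p1$probability, p1b$probability)
  expect_error(predict_p1(fit, list(group = "b"), t = 5, window = 5,
                          events = 2, recurrence_times = c(3, 1)),
               "strictly increasing")
  expect_error(predict_p1(fit, list(group = "b"), t = 5, window = 5,
                          events = 1, recurrence_times = c(1, 2)),
               "events = 1")
})

test_that("Monte-Carlo intervals are reproducible and collapse without noise", {
  fit <- fit_once()
  c1 <- prediction_confidence_interval(fit, list(group = "b"), t = 4,
                                       window = 4, events = 1,
                                       n_draws = 150, seed = 9)
  c2 <- prediction_confidence_interval(fit, list(group = "b"), t = 4,
                                       window = 4, events = 1,
                                       n_draws = 150, seed = 9)
  expect_identical(c1$ci_low, c2$ci_low)
  expect_identical(c1$ci_high, c2$ci_high)
  expect_true(c1$ci_low <= c1$probability &&
                c1$probability <= c1$ci_high)
  expect_true(all(c(c1$ci_low, c1$ci_high) >= 0 &
                    c(c1$ci_low, c1$ci_high) <= 1))
  # zero covariance degenerates to the point estimate
  flat <- fit
  flat$vcov[] <- 0
  c0 <- prediction_confidence_interval(flat, list(group = "b"), t = 4,
                                       window = 4, events = 1,
                                       n_draws = 120, seed = 1)
  expect_equal(c0$ci_low, c0$probability, tolerance = 1e-12)
  expect_equal(c0$ci_high, c0$probability, tolerance = 1e-12)
})

test_that("interval coverage is near nominal on refitted cohorts", {
  # reduced-scale coverage study: true window probability vs 95% MC bands
  scn <- toy_scenario(n = 300, theta = 1, alpha = 2)
  truth <- list(theta = 1, alpha = 2,
                beta_R = c("group=b" = log(2)),
                beta_D = c("group=b" = log(2)),
                baseline_R = scn$baseline_R, baseline_D = scn$baseline_D)
  p_true <- jfrail:::predict_prob_core(truth, 1, 1, t = 4, w = 4, J = 1,
                                       kind = "P1")
  hits <- 0
  R <- 20
  for (r in seq_len(R)) {
    co <- simulate_cohort(scn, 7000 + r)
    cp <- build_counting_process(co, scenario_design(scn))
    f <- tryCatch(fit_joint_model(cp, nodes = 24), error = function(e) NULL)
    if (is.null(f) || f$convergence$status != "converged") next
    ci <- prediction_confidence_interval(f, list(group = "b"), t = 4,
                                         window = 4, events = 1,
                                         n_draws = 200, seed = r)
    hits <- hits + (ci$ci_low <= p_true && p_true <= ci$ci_high)
  }
  # binomial slack around 0.95 at R = 20
  expect_gte(hits / R, 0.75)
})

test_that("prediction curves return tidy grids", {
  fit <- fit_once()
  cu <- prediction_curve(fit, list(group = "a"), t = 3,
                         windows = c(1, 2, 3), events = 0, kind = "P2")
  expect_equal(nrow(cu), 3)
  expect_equal(cu$kind, rep("P2", 3))
  expect_true(all(diff(cu$probability) >= 0))
})
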