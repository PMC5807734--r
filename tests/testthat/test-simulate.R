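test_that("simulated cohorts are reproducible and pass all invariants", {
  scn <- scenario_preset("smoke")
  c1 <- simulate_cohort(scn, 42)
  c2 <- simulate_cohort(scn, 42)
  f1 <- tempfile(); f2 <- tempfile()
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  c3 <- simulate_cohort(scn, 43)
  expect_false(identical(c1$subjects$terminal_time,
                         c3$subjects$terminal_time))
  validate_cohort(c1)
  # artifact generation produces prep material for the cohort module
  expect_true(any(c1$subjects$in_situ))
  expect_true(any(c1$subjects$metastatic_dx))
  expect_true(any(!c1$events$confirmed) || any(!c1$events$type_known))
})

test_that("event counts match the Poisson closed form without death", {
  # constant recurrence hazard 0.3, no death, horizon 5 -> mean count 1.5
  scn <- scenario(2000, theta = 0, alpha = 1,
                  baseline_R = weibull_baseline(1, 1 / 0.3),
                  baseline_D = piecewise_baseline(numeric(0), 0),
                  horizon = 5)
  co <- simulate_cohort(scn, 7)
  expect_true(all(co$subjects$terminal_status == "censored"))
  m <- nrow(co$events) / 2000
  se <- sqrt(1.5 / 2000)
  expect_lt(abs(m - 1.5), 3 * se)
})

test_that("death marginal matches the gamma Laplace transform at alpha 1", {
  # Lambda_D(t) = 0.1 t, theta = 1, t = 5: P(death by 5) = 1 - 1/1.5
  scn <- scenario(4000, theta = 1, alpha = 1,
                  baseline_R = piecewise_baseline(numeric(0), 1e-8),
                  baseline_D = weibull_baseline(1, 10),
                  horizon = 5)
  co <- simulate_cohort(scn, 13)
  p <- mean(co$subjects$terminal_status == "death")
  tgt <- 1 - (1 + 1 * 0.5)^(-1)
  expect_lt(abs(p - tgt), 3 * sqrt(tgt * (1 - tgt) / 4000))
})

test_that("a recurrence hazard ratio of two doubles mean event counts", {
  scn <- scenario(4000, theta = 0, alpha = 1,
                  baseline_R = weibull_baseline(1, 1 / 0.15),
                  baseline_D = piecewise_baseline(numeric(0), 0),
                  covariates = list(scenario_covariate(
                    "g", c("a", "b"), c(0.5, 0.5),
                    log_hr_recurrence = c(b = log(2)))),
                  horizon = 6, cap = 50)
  co <- simulate_cohort(scn, 29)
  cnt <- table(factor(co$events$subject_id, levels = co$subjects$subject_id))
  ratio <- mean(cnt[co$subjects$g == "b"]) / mean(cnt[co$subjects$g == "a"])
  expect_lt(abs(ratio - 2), 0.25)
})

test_that("the paper preset carries the published parameter vector", {
  est <- breast_joint_estimates()
  expect_equal(est$theta, 1.01)
  expect_equal(est$alpha, 4.29)
  expect_equal(unname(est$hr_recurrence["receptors=neg_neg"]), 2.14)
  expect_equal(unname(est$hr_death["size=ge2"]), 4.70)
  for (fr in est$frequencies) expect_equal(sum(fr), 1, tolerance = 1e-6)
  scn <- scenario_preset("paper", n_subjects = 500)
  expect_equal(scn$theta, 1.01)
  expect_equal(scn$alpha, 4.29)
  cvn <- vapply(scn$covariates, function(cv) cv$name, character(1))
  expect_setequal(cvn, names(breast_cohort_codebook()))
  mht <- scn$covariates[[which(cvn == "mht")]]
  expect_equal(unname(mht$log_hr_recurrence["yes"]), log(0.75))
  expect_null(mht$log_hr_death)
})

test_that("calibration hits the requested marginal frequencies", {
  scn <- scenario_preset("paper", n_subjects = 4000)
  co <- simulate_cohort(scn, 99)
  frac_rec <- mean(table(factor(co$events$subject_id,
    levels = co$subjects$subject_id)) >= 1)
  frac_death <- mean(co$subjects$terminal_status == "death")
  expect_lt(abs(frac_rec - 0.18), 0.025)
  expect_lt(abs(frac_death - 0.095), 0.02)
})

test_that("scenario round-trips through fitted or printed estimates", {
  tpl <- toy_scenario(n = 200)
  est <- list(theta = 0.7, alpha = 2.1,
              beta_R = c("group=b" = 0.6), beta_D = c("group=b" = 0.4),
              baseline_R = weibull_baseline(1.1, 7),
              baseline_D = weibull_baseline(0.9, 30))
  scn <- scenario_from_fitted(est, tpl)
  expect_equal(scn$theta, 0.7)
  expect_equal(scn$alpha, 2.1)
  expect_equal(unname(scn$covariates[[1]]$log_hr_recurrence["b"]), 0.6)
  expect_equal(scn$baseline_D$scale, 30)
  # identity: a scenario's own parameters return an equal scenario
  own <- list(theta = tpl$theta, alpha = tpl$alpha,
              beta_R = c("group=b" = tpl$covariates[[1]]$log_hr_recurrence[["b"]]),
              beta_D = c("group=b" = tpl$covariates[[1]]$log_hr_death[["b"]]),
              baseline_R = tpl$baseline_R, baseline_D = tpl$baseline_D)
  scn2 <- scenario_from_fitted(own, tpl)
  expect_equal(scn2$theta, tpl$theta)
  expect_equal(scn2$covariates[[1]]$log_hr_recurrence,
               tpl$covariates[[1]]$log_hr_recurrence)
  expect_error(scenario_from_fitted(list(theta = 1), tpl),
               "incomplete parameter set")
})
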