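# jfrail

Joint frailty modelling of cancer recurrences and death, with dynamic
individual prediction of death from the relapse history.

## The problem

After a first invasive breast cancer, women may experience successive
recurrent events — locoregional recurrence, distant metastasis, second
primary breast cancer — and may die. The two processes are dependent:
relapse-prone disease kills sooner, and death stops the recurrent
process, so treating either as independent censoring biases both
analyses. Cox models that censor at the first relapse also throw away
the later history, which is exactly what a clinician wants to condition
on when updating a prognosis.

`jfrail` is for biostatisticians and epidemiologists who need to

- prepare long-format recurrence cohorts with the standard filtering
  rules (eligibility, censoring at unconfirmed events, imputation of
  metastases reported only at death, follow-up truncation,
  complete-case selection), with audited exclusion logs;
- fit a **joint gamma-frailty model** for the recurrent and terminal
  processes;
- compute **dynamic predictions** of death over a window given the
  number of relapses so far, with Monte-Carlo confidence intervals;
- evaluate those predictions with an **IPCW Brier score** against a
  frailty-free comparator;
- **simulate** cohorts from the assumed data-generating process,
  including a preset encoding a published breast-cancer parameter
  vector.

## The model

Each subject carries a latent frailty `u ~ Gamma(mean 1, variance θ)`.
Conditional on `u` and covariates, the recurrence intensity on the
calendar timescale and the death hazard are

    r(t | u) = u · r0(t) · exp(β'X_R)
    λ(t | u) = u^α · λ0(t) · exp(γ'X_D)

`θ` measures the clustering of recurrences within subjects; the power
`α` measures how strongly the same heterogeneity drives death (`α > 0`:
relapse-prone subjects die sooner). Baselines are Weibull or
piecewise-constant. The marginal likelihood integrates the frailty out
per subject; the integrals are evaluated with exact closed forms where
they exist (`α ∈ {0, 1}`) and otherwise with mode-matched generalized
Gauss–Laguerre quadrature (optimizer path) or adaptive quadrature on
the log-frailty scale (exposed likelihood and all predictions).
Estimation is box-constrained quasi-Newton with an analytic
Fisher-identity score. The dynamic prediction

    P1(t, w) = P(death in (t, t+w] | alive at t, J recurrences by t, X)

conditions on the observed history; `P2` ignores it. See the methods
vignette (`vignettes/jfrail-methods.Rmd`) for formulas, numerics and
design decisions.

## Worked example

Simulate a cohort from the packaged scenario that encodes the published
joint-model estimates (θ = 1.01, α = 4.29, both submodels' hazard
ratios), prepare it, fit, predict and validate:

```r
library(jfrail)

scn  <- scenario_preset("paper", n_subjects = 2000)
co   <- simulate_cohort(scn, seed = 42)
prep <- prepare_cohort(co)
cp   <- build_counting_process(prep$cohort, scenario_design(scn))
fit  <- fit_joint_model(cp, nodes = 32)
fit
#> Joint frailty model fit (converged)
#>   subjects 2000, recurrences 473, deaths 187
#>   log-likelihood -2996.105
#>   theta 1.321, alpha 2.836
```

The fitted frailty variance (1.32, se 0.22) and power (2.84, se 0.95)
recover the generating values within sampling error, and the
hazard-ratio table reads like a standard regression summary — for
example double-negative hormone receptors multiply the recurrence
hazard by 2.27 (95% CI 1.71–3.01) against a generating value of 2.14:

```r
w <- wald_summary(fit)
head(subset(w$coefficients, submodel == "recurrence",
            c(term, hr, ci_low, ci_high, p)), 4)
#>                term    hr ci_low ci_high        p
#> 1 receptors=pos_neg 1.088  0.812    1.46 5.70e-01
#> 2 receptors=neg_pos 0.386  0.135    1.10 7.54e-02
#> 3 receptors=neg_neg 2.267  1.708    3.01 1.44e-08
#> 4    grade=moderate 1.704  1.183    2.45 4.20e-03
```

Dynamic prediction for the medium-risk profile at landmark 5 years,
window 5 years, as the relapse count grows — the probability of death
rises steeply with each observed recurrence, while the naive P2 (which
ignores the history) sits near the no-relapse value:

```r
for (J in 0:2)
  print(prediction_confidence_interval(fit, "medium", t = 5, window = 5,
                                       events = J, n_draws = 300, seed = 1))
#> P1(t=5, w=5, J=0) = 0.014 (95% MC CI 0.006, 0.027)
#> P1(t=5, w=5, J=1) = 0.053 (95% MC CI 0.024, 0.089)
#> P1(t=5, w=5, J=2) = 0.110 (95% MC CI 0.043, 0.165)
predict_p2(fit, "medium", t = 5, window = 5)
#> P2(t=5, w=5)      = 0.022
```

Prediction-error comparison against a frailty-free fit (IPCW Brier
score at the same landmark; lower is better, P1 uses the history):

```r
free <- fit_joint_model(cp, theta_zero = TRUE)
prediction_error_curve(fit, free, cp, t = 5, windows = 5)
#>   t window    predictor    epe n_at_risk effective_n
#> 1 5      5           P1 0.0241      1408         885
#> 2 5      5           P2 0.0243      1408         885
#> 3 5      5 frailty_free 0.0244      1408         885
```

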