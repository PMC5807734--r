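#' Pipeline stages with config, logging and seeds
#'
#' `run_stage()` is the single programmatic entry point wiring the
#' pipeline stages: `simulate` (scenario to cohort CSV), `prepare`
#' (preparation rules, exclusion logs, summary tables), `fit` (joint or
#' frailty-free model to JSON), `predict` (dynamic prediction curves),
#' `validate` (IPCW prediction-error curves) and `report` (hazard-ratio
#' and summary tables from artifacts).  Every stage writes a JSON run log
#' next to its outputs with the seed, a hash of the configuration, the
#' package version and the output counts.  A thin command-line wrapper
#' over this function ships in `inst/cli/jfrail`.
#'
#' @param config a named list (or path to a YAML file) with `command` and
#'   stage options; see Details.
#' @details Common fields: `command`, `out` (output directory), `seed`.
#'   Stage fields: `simulate`: `scenario` (preset name or YAML),
#'   `n_subjects`; `prepare`: `cohort` (CSV), `schema`, `horizon`,
#'   `complete_case`; `fit`: `cohort`, `schema`, `recurrent`, `death`
#'   (covariate names), `baseline`, `nodes`, `theta_zero`; `predict`:
#'   `model` (JSON), `profile`, `t`, `windows`, `events`, `kind`,
#'   `ci_draws`; `validate`: `model`, `model_free`, `cohort`, `schema`,
#'   `t`, `windows`; `report`: `model` and/or `cohort`.
#' @return invisibly, a named list of artifact paths.
#' @export
run_stage <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cmd <- config$command
  if (is.null(cmd) || !cmd %in% c("simulate", "prepare", "fit", "predict",
                                  "validate", "report"))
    stop("unknown or missing command: ", cmd %||% "<none>")
  out_dir <- config$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  artifacts <- switch(cmd,
    simulate = stage_simulate(config, out_dir, seed),
    prepare = stage_prepare(config, out_dir),
    fit = stage_fit(config, out_dir),
    predict = stage_predict(config, out_dir, seed),
    validate = stage_validate(config, out_dir),
    report = stage_report(config, out_dir))
  log_path <- file.path(out_dir, paste0(cmd, "_run_log.json"))
  jsonlite::write_json(
    list(command = cmd, seed = seed, config = config,
         config_hash = config_hash(config),
         package = "jfrail",
         version = as.character(utils::packageVersion("jfrail")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         artifacts = artifacts),
    log_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  artifacts$run_log <- log_path
  invisible(artifacts)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

load_scenario <- function(x, n_subjects = NULL) {
  if (inherits(x, "jf_scenario")) return(x)
  if (x %in% c("paper", "null", "smoke"))
    return(scenario_preset(x, n_subjects = n_subjects))
  sc <- yaml::read_yaml(x)
  covs <- lapply(sc$covariates, function(cv)
    scenario_covariate(cv$name, unlist(cv$levels), unlist(cv$probs),
                       log_hr_recurrence = unlist(cv$log_hr_recurrence),
                       log_hr_death = unlist(cv$log_hr_death)))
  bl <- function(b) {
    if (b$family == "weibull") weibull_baseline(b$shape, b$scale)
    else piecewise_baseline(unlist(b$cuts), unlist(b$rates))
  }
  scenario(n_subjects %||% sc$n_subjects, sc$theta, sc$alpha,
           bl(sc$baseline_R), bl(sc$baseline_D), covs, sc$horizon,
           dropout = unlist(sc$dropout), cap = sc$cap %||% 10,
           prep = sc$prep %||% list())
}

stage_simulate <- function(config, out_dir, seed) {
  scn <- load_scenario(config$scenario %||% "smoke", config$n_subjects)
  cohort <- simulate_cohort(scn, seed)
  p <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, p)
  ps <- file.path(out_dir, "schema.yaml")
  write_schema(cohort, ps)
  list(cohort = p, schema = ps)
}

stage_prepare <- function(config, out_dir) {
  cohort <- read_cohort(config$cohort, config$schema)
  prep <- prepare_cohort(cohort, horizon = config$horizon,
                         complete_case_covariates = config$complete_case)
  p <- file.path(out_dir, "prepared.csv")
  write_cohort(prep$cohort, p)
  pl <- file.path(out_dir, "exclusion_log.json")
  jsonlite::write_json(lapply(prep$logs, function(l)
    list(input_n = l$input_n, output_n = l$output_n, rules = l$rules)),
    pl, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  sm <- summarize_cohort(prep$cohort)
  p1 <- file.path(out_dir, "summary_recurrences.csv")
  utils::write.csv(sm$by_count, p1, row.names = FALSE)
  p2 <- file.path(out_dir, "summary_types.csv")
  utils::write.csv(sm$by_type, p2, row.names = FALSE)
  list(prepared = p, exclusion_log = pl, summary_recurrences = p1,
       summary_types = p2)
}

stage_fit <- function(config, out_dir) {
  cohort <- read_cohort(config$cohort, config$schema)
  design <- make_design(cohort$codebook,
                        recurrent = unlist(config$recurrent) %||% character(),
                        death = unlist(config$death) %||% character())
  cp <- build_counting_process(cohort, design)
  fit <- fit_joint_model(cp, baseline = config$baseline %||% "weibull",
                         theta_zero = isTRUE(config$theta_zero),
                         nodes = config$nodes %||% 32)
  p <- file.path(out_dir, if (isTRUE(config$theta_zero))
    "fitted_free.json" else "fitted.json")
  write_fitted_model(fit, p)
  pw <- NULL
  if (fit$convergence$status == "converged" && !is.null(fit$vcov)) {
    w <- wald_summary(fit)
    if (!is.null(w$coefficients)) {
      pw <- file.path(out_dir, "hazard_ratios.csv")
      utils::write.csv(w$coefficients, pw, row.names = FALSE)
    }
  }
  c(list(model = p), if (!is.null(pw)) list(hazard_ratios = pw))
}

stage_predict <- function(config, out_dir, seed) {
  fit <- read_fitted_model(config$model)
  windows <- unlist(config$windows) %||% config$window
  curves <- prediction_curve(
    fit, config$profile %||% "medium", t = config$t %||% 5,
    windows = windows, events = config$events %||% 0,
    kind = config$kind %||% "P1",
    ci = !is.null(config$ci_draws),
    n_draws = config$ci_draws %||% 500, seed = seed)
  p <- file.path(out_dir, "predictions.csv")
  utils::write.csv(curves, p, row.names = FALSE)
  pj <- file.path(out_dir, "predictions.json")
  jsonlite::write_json(curves, pj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  list(predictions_csv = p, predictions_json = pj)
}

stage_validate <- function(config, out_dir) {
  fit <- read_fitted_model(config$model)
  fit_free <- if (!is.null(config$model_free))
    read_fitted_model(config$model_free)
  cohort <- read_cohort(config$cohort, config$schema)
  cp <- build_counting_process(cohort, fit$design)
  curve <- prediction_error_curve(fit, fit_free, cp,
                                  t = config$t %||% 5,
                                  windows = unlist(config$windows) %||% 5)
  p <- file.path(out_dir, "prediction_error.csv")
  utils::write.csv(curve, p, row.names = FALSE)
  list(prediction_error = p)
}

stage_report <- function(config, out_dir) {
  art <- list()
  if (!is.null(config$model)) {
    fit <- read_fitted_model(config$model)
    w <- wald_summary(fit)
    p <- file.path(out_dir, "report_hazard_ratios.csv")
    tab <- w$coefficients
    extra <- data.frame(term = c("theta", "alpha"), submodel = "frailty",
                        estimate = c(w$theta$estimate, w$alpha$estimate),
                        se = c(w$theta$se, w$alpha$se),
                        hr = NA, ci_low = NA, ci_high = NA,
                        p = c(w$theta$p, w$alpha$p),
                        stringsAsFactors = FALSE)
    if (!fit$theta_zero) tab <- rbind(tab, extra)
    utils::write.csv(tab, p, row.names = FALSE)
    art$hazard_ratios <- p
  }
  if (!is.null(config$cohort)) {
    cohort <- read_cohort(config$cohort, config$schema)
    sm <- summarize_cohort(cohort)
    p1 <- file.path(out_dir, "report_recurrences.csv")
    utils::write.csv(sm$by_count, p1, row.names = FALSE)
    p2 <- file.path(out_dir, "report_types.csv")
    utils::write.csv(sm$by_type, p2, row.names = FALSE)
    p3 <- file.path(out_dir, "report_gaps.csv")
    if (!is.null(sm$gaps)) utils::write.csv(sm$gaps, p3, row.names = FALSE)
    art$recurrences <- p1
    art$types <- p2
    if (!is.null(sm$gaps)) art$gaps <- p3
  }
  art
}
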