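#' Event-history cohorts
#'
#' A cohort holds one row per subject in `$subjects` (terminal time and
#' status, diagnosis flags, baseline covariate categories) and one row per
#' recurrent-event episode in `$events` (time in years since first
#' diagnosis, event type, confirmation flags).  A codebook declares the
#' category levels of every covariate, with the reference level first;
#' missing values are an explicit category (`"missing"` by default).
#'
#' @param subjects data.frame with columns `subject_id`, `terminal_time`
#'   (years, > 0), `terminal_status` (`"death"` or `"censored"`),
#'   logical `in_situ`, `metastatic_dx`, `mets_at_death_only`, plus one
#'   character column per covariate.
#' @param events data.frame with columns `subject_id`, `time` (years),
#'   `type` (`"locoregional"`, `"metastasis"`, `"second_primary"`),
#'   logical `confirmed` and `type_known`.
#' @param codebook named list; each element is a character vector of
#'   category levels, reference level first.
#' @param missing_label category label marking missingness.
#' @return an object of class `jf_cohort`.
#' @export
new_cohort <- function(subjects, events, codebook = NULL,
                       missing_label = "missing") {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  req_s <- c("subject_id", "terminal_time", "terminal_status",
             "in_situ", "metastatic_dx", "mets_at_death_only")
  if (!all(req_s %in% names(subjects)))
    stop("subjects is missing columns: ",
         paste(setdiff(req_s, names(subjects)), collapse = ", "))
  req_e <- c("subject_id", "time", "type", "confirmed", "type_known")
  if (!nrow(events)) {
    events <- data.frame(subject_id = character(), time = numeric(),
                         type = character(), confirmed = logical(),
                         type_known = logical(), stringsAsFactors = FALSE)
  }
  if (!all(req_e %in% names(events)))
    stop("events is missing columns: ",
         paste(setdiff(req_e, names(events)), collapse = ", "))
  covars <- setdiff(names(subjects), req_s)
  if (is.null(codebook)) {
    codebook <- lapply(covars, function(v) sort(unique(subjects[[v]])))
    names(codebook) <- covars
  }
  events <- events[order(match(events$subject_id, subjects$subject_id),
                         events$time), , drop = FALSE]
  rownames(events) <- NULL
  rownames(subjects) <- NULL
  x <- structure(list(subjects = subjects, events = events,
                      codebook = codebook, covariates = covars,
                      missing_label = missing_label),
                 class = "jf_cohort")
  validate_cohort(x)
}

#' Validate cohort invariants
#'
#' Checks, per subject: event times strictly increasing and positive,
#' terminal time positive and at least the last event time, a unique
#' terminal entry, covariate categories drawn from the codebook, and
#' `mets_at_death_only` only on deaths.  Errors name the offending
#' subject and invariant.
#'
#' @param x a `jf_cohort`.
#' @return `x`, invisibly usable in pipelines.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "jf_cohort"))
  s <- x$subjects; e <- x$events
  if (anyDuplicated(s$subject_id))
    stop("duplicate terminal entry for subject ",
         s$subject_id[duplicated(s$subject_id)][1])
  if (!all(s$terminal_status %in% c("death", "censored")))
    stop("invalid terminal_status for subject ",
         s$subject_id[!s$terminal_status %in% c("death", "censored")][1])
  if (any(bad <- !(s$terminal_time > 0)))
    stop("non-positive terminal time for subject ", s$subject_id[bad][1])
  if (nrow(e)) {
    if (any(bad <- !(e$time > 0)))
      stop("non-positive event time for subject ", e$subject_id[bad][1])
    unknown <- setdiff(e$subject_id, s$subject_id)
    if (length(unknown)) stop("event for unknown subject ", unknown[1])
    if (!all(e$type %in% c("locoregional", "metastasis", "second_primary")))
      stop("invalid event type for subject ",
           e$subject_id[!e$type %in%
             c("locoregional", "metastasis", "second_primary")][1])
    for (id in unique(e$subject_id)) {
      tt <- e$time[e$subject_id == id]
      if (is.unsorted(tt, strictly = TRUE))
        stop("event times not strictly increasing for subject ", id)
      term <- s$terminal_time[s$subject_id == id]
      if (max(tt) > term)
        stop("event after terminal time for subject ", id)
    }
  }
  for (v in x$covariates) {
    lv <- c(x$codebook[[v]], x$missing_label)
    if (any(bad <- !s[[v]] %in% lv))
      stop("covariate '", v, "' has category outside codebook for subject ",
           s$subject_id[bad][1])
  }
  invisible(x)
}

n_subjects <- function(x) nrow(x$subjects)

# ---- exclusion logs -------------------------------------------------------

new_exclusion_log <- function(input_n, rules, output_n) {
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  if (!nrow(rules))
    rules <- data.frame(rule = character(), removed = integer(),
                        modified = integer(), stringsAsFactors = FALSE)
  if (input_n - sum(rules$removed) != output_n)
    stop("exclusion log does not conserve counts")
  structure(list(input_n = input_n, rules = rules, output_n = output_n),
            class = "jf_exclusion_log")
}

#' @export
print.jf_exclusion_log <- function(x, ...) {
  cat(sprintf("Exclusion log: %d -> %d subjects\n", x$input_n, x$output_n))
  if (nrow(x$rules)) print(x$rules, row.names = FALSE)
  invisible(x)
}

# ---- preparation rules ----------------------------------------------------

#' Eligibility filter
#'
#' Removes subjects with in situ carcinoma at diagnosis, then subjects
#' metastatic at first diagnosis, logging each rule in order.
#'
#' @param cohort a validated `jf_cohort`.
#' @return list with the filtered `cohort` and an exclusion `log`.
#' @export
apply_eligibility_filter <- function(cohort) {
  stopifnot(inherits(cohort, "jf_cohort"))
  n0 <- n_subjects(cohort)
  drop1 <- cohort$subjects$in_situ
  keep1 <- cohort$subjects$subject_id[!drop1]
  drop2 <- cohort$subjects$metastatic_dx & !drop1
  keep <- cohort$subjects$subject_id[!(drop1 | cohort$subjects$metastatic_dx)]
  out <- subset_cohort(cohort, keep)
  log <- new_exclusion_log(
    n0,
    data.frame(rule = c("in_situ_at_diagnosis", "metastatic_at_diagnosis"),
               removed = c(sum(drop1), sum(drop2)),
               modified = c(0L, 0L)),
    n_subjects(out))
  list(cohort = out, log = log)
}

subset_cohort <- function(cohort, ids) {
  s <- cohort$subjects[cohort$subjects$subject_id %in% ids, , drop = FALSE]
  e <- cohort$events[cohort$events$subject_id %in% ids, , drop = FALSE]
  rownames(s) <- rownames(e) <- NULL
  cohort$subjects <- s
  cohort$events <- e
  cohort
}

#' Censor subjects at unconfirmed or type-unknown events
#'
#' For each subject whose earliest unconfirmed or type-unknown event is at
#' time `s`, all events at or after `s` are dropped and the subject is
#' censored at `s`; earlier confirmed events are kept.  Subjects censored
#' this way can no longer carry a metastasis-at-death flag.
#'
#' @inheritParams apply_eligibility_filter
#' @return list with modified `cohort` and `log` (counts modified, none
#'   removed).
#' @export
resolve_unconfirmed_events <- function(cohort) {
  stopifnot(inherits(cohort, "jf_cohort"))
  e <- cohort$events
  bad <- !e$confirmed | !e$type_known
  n_unconf <- 0L; n_unknown <- 0L
  if (any(bad)) {
    first <- do.call(rbind, lapply(split(which(bad), e$subject_id[bad]),
                                   function(ix) {
      i <- ix[which.min(e$time[ix])]
      data.frame(subject_id = e$subject_id[i], s = e$time[i],
                 reason = if (!e$confirmed[i]) "unconfirmed_event"
                          else "event_type_missing",
                 stringsAsFactors = FALSE)
    }))
    n_unconf <- sum(first$reason == "unconfirmed_event")
    n_unknown <- sum(first$reason == "event_type_missing")
    m <- match(cohort$subjects$subject_id, first$subject_id)
    hit <- !is.na(m)
    cohort$subjects$terminal_time[hit] <- first$s[m[hit]]
    cohort$subjects$terminal_status[hit] <- "censored"
    cohort$subjects$mets_at_death_only[hit] <- FALSE
    cut <- first$s[match(e$subject_id, first$subject_id)]
    keep <- is.na(cut) | e$time < cut
    cohort$events <- e[keep, , drop = FALSE]
    rownames(cohort$events) <- NULL
  }
  log <- new_exclusion_log(
    n_subjects(cohort),
    data.frame(rule = c("unconfirmed_event", "event_type_missing"),
               removed = c(0L, 0L),
               modified = c(n_unconf, n_unknown)),
    n_subjects(cohort))
  list(cohort = validate_cohort(cohort), log = log)
}

#' Impute metastases reported only at death
#'
#' For deaths flagged `mets_at_death_only`, inserts a confirmed metastasis
#' event 2 years before death when the delay since diagnosis is at least
#' 2 years, and 1 day (1/365.25 years) before death otherwise; the flag is
#' then cleared.
#'
#' @inheritParams apply_eligibility_filter
#' @return list with modified `cohort` and `log`.
#' @export
impute_terminal_metastases <- function(cohort) {
  stopifnot(inherits(cohort, "jf_cohort"))
  s <- cohort$subjects
  flag <- s$mets_at_death_only
  if (any(flag & s$terminal_status != "death"))
    stop("mets_at_death_only set for censored subject ",
         s$subject_id[flag & s$terminal_status != "death"][1])
  n2 <- 0L; n1 <- 0L
  if (any(flag)) {
    ins <- lapply(which(flag), function(i) {
      d <- s$terminal_time[i]
      if (d >= 2) { t <- d - 2; two <- TRUE }
      else { t <- max(d - DAY_YEARS, d / 2); two <- FALSE }
      # keep event times strictly increasing within the subject
      others <- cohort$events$time[cohort$events$subject_id == s$subject_id[i]]
      while (any(abs(others - t) < 1e-12)) t <- t + 1e-9
      data.frame(subject_id = s$subject_id[i], time = t,
                 type = "metastasis", confirmed = TRUE, type_known = TRUE,
                 two = two, stringsAsFactors = FALSE)
    })
    ins <- do.call(rbind, ins)
    n2 <- sum(ins$two); n1 <- sum(!ins$two)
    cohort$events <- rbind(cohort$events, ins[names(cohort$events)])
    cohort$events <- cohort$events[order(
      match(cohort$events$subject_id, s$subject_id), cohort$events$time), ,
      drop = FALSE]
    rownames(cohort$events) <- NULL
    cohort$subjects$mets_at_death_only <- FALSE
  }
  log <- new_exclusion_log(
    n_subjects(cohort),
    data.frame(rule = c("mets_imputed_2y_before_death",
                        "mets_imputed_1d_before_death"),
               removed = c(0L, 0L), modified = c(n2, n1)),
    n_subjects(cohort))
  list(cohort = validate_cohort(cohort), log = log)
}

#' Truncate follow-up at a horizon
#'
#' Drops events at or beyond the horizon (intervals are half-open, so an
#' event exactly at the horizon is dropped) and censors subjects whose
#' terminal time exceeds the horizon.
#'
#' @inheritParams apply_eligibility_filter
#' @param horizon positive truncation time (years).
#' @return the truncated cohort.
#' @export
truncate_follow_up <- function(cohort, horizon) {
  stopifnot(inherits(cohort, "jf_cohort"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("horizon must be a single positive number")
  keep <- cohort$events$time < horizon
  cohort$events <- cohort$events[keep, , drop = FALSE]
  rownames(cohort$events) <- NULL
  over <- cohort$subjects$terminal_time > horizon
  cohort$subjects$terminal_time[over] <- horizon
  cohort$subjects$terminal_status[over] <- "censored"
  cohort$subjects$mets_at_death_only[over] <- FALSE
  validate_cohort(cohort)
}

#' Complete-case selection
#'
#' Retains subjects with no missing category on any of the named
#' covariates; the log reports per-covariate missing counts (a subject
#' missing several covariates appears in each count but is removed once).
#'
#' @inheritParams apply_eligibility_filter
#' @param covariates character vector of covariate names to require.
#' @return list with filtered `cohort` and `log`.
#' @export
select_complete_cases <- function(cohort, covariates) {
  stopifnot(inherits(cohort, "jf_cohort"))
  unknown <- setdiff(covariates, cohort$covariates)
  if (length(unknown))
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  n0 <- n_subjects(cohort)
  if (!length(covariates)) {
    return(list(cohort = cohort,
                log = new_exclusion_log(n0, NULL, n0)))
  }
  miss <- vapply(covariates,
                 function(v) cohort$subjects[[v]] == cohort$missing_label,
                 logical(n0))
  miss <- matrix(miss, nrow = n0)
  drop <- rowSums(miss) > 0
  out <- subset_cohort(cohort, cohort$subjects$subject_id[!drop])
  if (!n_subjects(out))
    warning("complete-case selection removed every subject")
  rules <- data.frame(rule = paste0("missing_", covariates),
                      removed = 0L, modified = colSums(miss),
                      stringsAsFactors = FALSE)
  rules <- rbind(rules,
                 data.frame(rule = "incomplete_case", removed = sum(drop),
                            modified = 0L, stringsAsFactors = FALSE))
  list(cohort = out, log = new_exclusion_log(n0, rules, n_subjects(out)))
}

#' Standard preparation pipeline
#'
#' Applies, in order: eligibility filter, censoring at unconfirmed events,
#' imputation of terminal metastases, optional truncation, and optional
#' complete-case selection.
#'
#' @inheritParams apply_eligibility_filter
#' @param horizon optional truncation horizon (years).
#' @param complete_case_covariates optional covariate names for
#'   complete-case selection.
#' @return list with prepared `cohort` and a list of `logs` per stage.
#' @export
prepare_cohort <- function(cohort, horizon = NULL,
                           complete_case_covariates = NULL) {
  logs <- list()
  st <- apply_eligibility_filter(cohort)
  logs$eligibility <- st$log
  st <- resolve_unconfirmed_events(st$cohort)
  logs$unconfirmed <- st$log
  st <- impute_terminal_metastases(st$cohort)
  logs$terminal_metastases <- st$log
  cohort <- st$cohort
  if (!is.null(horizon)) cohort <- truncate_follow_up(cohort, horizon)
  if (!is.null(complete_case_covariates)) {
    st <- select_complete_cases(cohort, complete_case_covariates)
    logs$complete_cases <- st$log
    cohort <- st$cohort
  }
  list(cohort = cohort, logs = logs)
}

# ---- summaries ------------------------------------------------------------

med_iqr <- function(x) {
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Cohort summary tables
#'
#' Counts of subjects by number of recurrences (0, 1, 2, 3+) with the
#' median \[IQR\] time from diagnosis to the order-matching event, counts
#' and times by event type, death counts, and gap times between
#' consecutive events by transition order and end-of-period event type.
#'
#' @inheritParams apply_eligibility_filter
#' @return an object of class `jf_cohort_summary` (a list of data frames).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "jf_cohort"))
  s <- cohort$subjects; e <- cohort$events
  n <- n_subjects(cohort)
  cnt <- table(factor(e$subject_id, levels = s$subject_id))
  grp <- cut(as.integer(cnt), breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
             labels = c("0", "1", "2", "3+"))
  by_count <- data.frame(n_recurrences = levels(grp),
                         n_women = as.integer(table(grp)),
                         stringsAsFactors = FALSE)
  by_count$pct <- if (n) 100 * by_count$n_women / n else rep(NA_real_, 4)
  # time from diagnosis to the order-matching event (1st, 2nd, 3rd)
  ord <- if (nrow(e)) stats::ave(e$time, e$subject_id, FUN = seq_along)
         else integer(0)
  tm <- t(vapply(1:3, function(k) {
    ids <- names(cnt)[if (k < 3) as.integer(cnt) == k else as.integer(cnt) >= 3]
    med_iqr(e$time[ord == k & e$subject_id %in% ids])
  }, numeric(3)))
  by_count <- cbind(by_count, rbind(c(NA, NA, NA), tm))
  by_type <- do.call(rbind, lapply(
    c("locoregional", "metastasis", "second_primary"), function(ty) {
      tt <- e$time[e$type == ty]
      data.frame(type = ty, n_events = length(tt),
                 pct = if (nrow(e)) 100 * length(tt) / nrow(e) else NA_real_,
                 t(med_iqr(tt)), stringsAsFactors = FALSE)
    }))
  all_rec <- data.frame(type = "all_recurrences", n_events = nrow(e),
                        pct = if (nrow(e)) 100 else NA_real_,
                        t(med_iqr(e$time)), stringsAsFactors = FALSE)
  by_type <- rbind(by_type, all_rec)
  dt <- s$terminal_time[s$terminal_status == "death"]
  deaths <- data.frame(n_deaths = length(dt),
                       pct = if (n) 100 * length(dt) / n else NA_real_,
                       t(med_iqr(dt)))
  # gap times by transition order and end-period event type
  gaps <- do.call(rbind, lapply(seq_len(n), function(i) {
    id <- s$subject_id[i]
    tt <- e$time[e$subject_id == id]
    ty <- e$type[e$subject_id == id]
    times <- c(0, tt, s$terminal_time[i])
    types <- c(ty, ifelse(s$terminal_status[i] == "death", "death", "censored"))
    data.frame(transition = seq_along(types), end_type = types,
               gap = diff(times), stringsAsFactors = FALSE)
  }))
  gap_table <- NULL
  if (!is.null(gaps) && nrow(gaps)) {
    gap_table <- do.call(rbind, lapply(
      split(gaps, list(gaps$transition, gaps$end_type), drop = TRUE),
      function(g) data.frame(transition = g$transition[1],
                             end_type = g$end_type[1], n = nrow(g),
                             mean = mean(g$gap), sd = stats::sd(g$gap),
                             t(med_iqr(g$gap)), stringsAsFactors = FALSE)))
    gap_table <- gap_table[order(gap_table$transition, gap_table$end_type), ]
    rownames(gap_table) <- NULL
  }
  structure(list(n_subjects = n, by_count = by_count, by_type = by_type,
                 deaths = deaths, gaps = gap_table),
            class = "jf_cohort_summary")
}

#' @export
print.jf_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d subjects\n\nRecurrences per woman:\n", x$n_subjects))
  print(x$by_count, row.names = FALSE, digits = 3)
  cat("\nEvents by type:\n")
  print(x$by_type, row.names = FALSE, digits = 3)
  cat("\nDeaths:\n")
  print(x$deaths, row.names = FALSE, digits = 3)
  invisible(x)
}

# ---- I/O ------------------------------------------------------------------

#' Read and write cohorts as delimited text
#'
#' The on-disk format has one row per episode: `subject_id`, `time_years`,
#' `event_type` in `locoregional`/`metastasis`/`second_primary`/`death`/
#' `censor`, `confirmed`, `type_known` (0/1), diagnosis flags `in_situ`,
#' `metastatic_at_diagnosis`, `mets_at_death_only` (0/1, constant within
#' subject), and one column per covariate.  Every subject has exactly one
#' terminal (`death`/`censor`) row.  An optional YAML schema declares the
#' covariate codebook (`covariates: {var: {levels: [...], ref: ...}}`).
#'
#' @param file path to a CSV file.
#' @param schema optional path to a YAML schema file.
#' @return `read_cohort`: a `jf_cohort`; `write_cohort`: `file`, invisibly.
#' @export
read_cohort <- function(file, schema = NULL) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("subject_id", "time_years", "event_type", "confirmed",
           "type_known", "in_situ", "metastatic_at_diagnosis",
           "mets_at_death_only")
  if (!all(req %in% names(d)))
    stop("cohort file is missing columns: ",
         paste(setdiff(req, names(d)), collapse = ", "))
  d$subject_id <- as.character(d$subject_id)
  covars <- setdiff(names(d), req)
  term <- d[d$event_type %in% c("death", "censor"), , drop = FALSE]
  if (anyDuplicated(term$subject_id))
    stop("multiple terminal rows for subject ",
         term$subject_id[duplicated(term$subject_id)][1])
  missing_term <- setdiff(d$subject_id, term$subject_id)
  if (length(missing_term))
    stop("no terminal row for subject ", missing_term[1])
  subjects <- data.frame(subject_id = term$subject_id,
                         terminal_time = term$time_years,
                         terminal_status = ifelse(term$event_type == "death",
                                                  "death", "censored"),
                         in_situ = term$in_situ == 1,
                         metastatic_dx = term$metastatic_at_diagnosis == 1,
                         mets_at_death_only = term$mets_at_death_only == 1,
                         stringsAsFactors = FALSE)
  for (v in covars) subjects[[v]] <- as.character(term[[v]])
  ep <- d[!d$event_type %in% c("death", "censor"), , drop = FALSE]
  events <- data.frame(subject_id = ep$subject_id, time = ep$time_years,
                       type = ep$event_type, confirmed = ep$confirmed == 1,
                       type_known = ep$type_known == 1,
                       stringsAsFactors = FALSE)
  codebook <- NULL
  missing_label <- "missing"
  if (!is.null(schema)) {
    sc <- read_schema(schema)
    codebook <- sc$codebook
    missing_label <- sc$missing_label
  }
  new_cohort(subjects, events, codebook, missing_label)
}

#' @rdname read_cohort
#' @param cohort a `jf_cohort`.
#' @export
write_cohort <- function(cohort, file) {
  stopifnot(inherits(cohort, "jf_cohort"))
  s <- cohort$subjects
  base <- function(ids) {
    m <- match(ids, s$subject_id)
    out <- data.frame(in_situ = as.integer(s$in_situ[m]),
                      metastatic_at_diagnosis = as.integer(s$metastatic_dx[m]),
                      mets_at_death_only = as.integer(s$mets_at_death_only[m]),
                      stringsAsFactors = FALSE)
    for (v in cohort$covariates) out[[v]] <- s[[v]][m]
    out
  }
  ev <- cohort$events
  rows_e <- cbind(data.frame(subject_id = ev$subject_id,
                             time_years = ev$time, event_type = ev$type,
                             confirmed = as.integer(ev$confirmed),
                             type_known = as.integer(ev$type_known),
                             stringsAsFactors = FALSE),
                  base(ev$subject_id))
  rows_t <- cbind(data.frame(subject_id = s$subject_id,
                             time_years = s$terminal_time,
                             event_type = ifelse(s$terminal_status == "death",
                                                 "death", "censor"),
                             confirmed = 1L, type_known = 1L,
                             stringsAsFactors = FALSE),
                  base(s$subject_id))
  all <- rbind(rows_e, rows_t)
  all <- all[order(match(all$subject_id, s$subject_id), all$time_years), ]
  utils::write.csv(all, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname read_cohort
#' @export
read_schema <- function(file) {
  sc <- yaml::read_yaml(file)
  cb <- lapply(sc$covariates, function(v) {
    lv <- as.character(v$levels)
    ref <- v$ref %||% lv[1]
    c(ref, setdiff(lv, ref))
  })
  list(codebook = cb, missing_label = sc$missing_label %||% "missing")
}

#' @rdname read_cohort
#' @export
write_schema <- function(cohort, file) {
  stopifnot(inherits(cohort, "jf_cohort"))
  sc <- list(missing_label = cohort$missing_label,
             covariates = lapply(cohort$codebook, function(lv)
               list(levels = as.list(lv), ref = lv[1])))
  yaml::write_yaml(sc, file)
  invisible(file)
}

#' @export
print.jf_cohort <- function(x, ...) {
  cat(sprintf("jf_cohort: %d subjects, %d recurrent-event episodes, %d deaths\n",
              n_subjects(x), nrow(x$events),
              sum(x$subjects$terminal_status == "death")))
  if (length(x$covariates))
    cat("covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}
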