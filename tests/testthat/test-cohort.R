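test_that("cohort validation names the offending subject and invariant", {
  s <- rbind(subj_row("a", 5), subj_row("b", 3, "death"))
  expect_s3_class(new_cohort(s, empty_events()), "jf_cohort")
  expect_error(new_cohort(rbind(s, subj_row("a", 2)), empty_events()),
               "duplicate terminal entry.*a")
  expect_error(new_cohort(subj_row("c", -1), empty_events()),
               "non-positive terminal time.*c")
  expect_error(new_cohort(s, event_row("a", 6)),
               "event after terminal time.*a")
  e <- rbind(event_row("a", 2), event_row("a", 2))
  expect_error(new_cohort(s, e), "strictly increasing.*a")
  s2 <- subj_row("a", 5, grade = "odd")
  expect_error(new_cohort(s2, empty_events(),
                          codebook = list(grade = c("well", "poor"))),
               "outside codebook.*a")
})

test_that("eligibility filter removes in situ then metastatic diagnoses", {
  set.seed(1)
  n <- 5690
  s <- subj_row(sprintf("w%04d", 1:n), runif(n, 1, 15))
  s$in_situ[1:735] <- TRUE
  s$metastatic_dx[736:764] <- TRUE
  co <- new_cohort(s, empty_events())
  out <- apply_eligibility_filter(co)
  expect_equal(nrow(out$cohort$subjects), 4926)
  expect_equal(out$log$rules$removed, c(735L, 29L))
  expect_equal(out$log$rules$rule,
               c("in_situ_at_diagnosis", "metastatic_at_diagnosis"))
  expect_false(any(out$cohort$subjects$in_situ))
  expect_false(any(out$cohort$subjects$metastatic_dx))

  # empty roster
  emp <- apply_eligibility_filter(new_cohort(subj_row(character(0),
    numeric(0)), empty_events()))
  expect_equal(emp$log$input_n, 0L)
  expect_equal(sum(emp$log$rules$removed), 0L)

  # small enumerated fixture: 10 records, 2 in situ, 1 metastatic
  s10 <- subj_row(letters[1:10], rep(5, 10))
  s10$in_situ[1:2] <- TRUE
  s10$metastatic_dx[3] <- TRUE
  o10 <- apply_eligibility_filter(new_cohort(s10, empty_events()))
  expect_equal(nrow(o10$cohort$subjects), 7)
  expect_equal(o10$log$rules$removed, c(2L, 1L))
})

test_that("unconfirmed or type-unknown events censor the subject at the event", {
  s <- rbind(subj_row("a", 6), subj_row("b", 8, "death"),
             subj_row("c", 7))
  e <- rbind(event_row("a", 1.0), event_row("a", 3.2, confirmed = FALSE),
             event_row("b", 2.0),
             event_row("c", 0.5, type_known = FALSE), event_row("c", 2.0))
  out <- resolve_unconfirmed_events(new_cohort(s, e))
  co <- out$cohort
  # subject a keeps the confirmed event, censored at the unconfirmed one
  expect_equal(co$events$time[co$events$subject_id == "a"], 1.0)
  expect_equal(co$subjects$terminal_time[co$subjects$subject_id == "a"], 3.2)
  expect_equal(co$subjects$terminal_status[co$subjects$subject_id == "a"],
               "censored")
  # subject b untouched
  expect_equal(co$subjects$terminal_status[co$subjects$subject_id == "b"],
               "death")
  expect_equal(co$events$time[co$events$subject_id == "b"], 2.0)
  # subject c: earliest offending event wipes the later confirmed one
  expect_equal(sum(co$events$subject_id == "c"), 0L)
  expect_equal(co$subjects$terminal_time[co$subjects$subject_id == "c"], 0.5)
  expect_equal(out$log$rules$modified, c(1L, 1L))
})

test_that("metastases reported only at death are imputed per the delay rule", {
  s <- rbind(subj_row("a", 5.0, "death", mets_flag = TRUE),
             subj_row("b", 1.5, "death", mets_flag = TRUE),
             subj_row("c", 4.0, "death"))
  out <- impute_terminal_metastases(new_cohort(s, empty_events()))
  ea <- out$cohort$events[out$cohort$events$subject_id == "a", ]
  expect_equal(ea$time, 3.0)
  expect_equal(ea$type, "metastasis")
  eb <- out$cohort$events[out$cohort$events$subject_id == "b", ]
  expect_equal(eb$time, 1.5 - 1 / 365.25)
  expect_equal(nrow(out$cohort$events[out$cohort$events$subject_id == "c", ]),
               0L)
  expect_false(any(out$cohort$subjects$mets_at_death_only))
  expect_equal(out$log$rules$modified, c(1L, 1L))
  # flag on a censored subject is a validation error
  bad <- new_cohort(subj_row("z", 3), empty_events())
  bad$subjects$mets_at_death_only <- TRUE
  expect_error(impute_terminal_metastases(bad), "censored subject z")
})

test_that("follow-up truncation censors at the horizon, half-open", {
  s <- rbind(subj_row("a", 12.3, "death"), subj_row("b", 7.2),
             subj_row("c", 11, "death"))
  e <- rbind(event_row("a", 4), event_row("a", 11), event_row("c", 10.0))
  co <- truncate_follow_up(new_cohort(s, e), 10)
  expect_equal(co$events$time[co$events$subject_id == "a"], 4)
  expect_equal(co$subjects$terminal_time[co$subjects$subject_id == "a"], 10)
  expect_equal(co$subjects$terminal_status[co$subjects$subject_id == "a"],
               "censored")
  # untouched subject within horizon
  expect_equal(co$subjects$terminal_time[co$subjects$subject_id == "b"], 7.2)
  # event exactly at the horizon is dropped
  expect_equal(sum(co$events$subject_id == "c"), 0L)
  expect_error(truncate_follow_up(co, -1), "positive")
})

test_that("complete-case selection logs per-covariate missingness", {
  s <- subj_row(letters[1:5], rep(5, 5), grade = c("well", "missing",
    "missing", "poor", "well"), size = c("lt2", "lt2", "missing", "lt2",
    "lt2"))
  co <- new_cohort(s, empty_events(),
                   codebook = list(grade = c("well", "poor"),
                                   size = c("lt2", "ge2")))
  out <- select_complete_cases(co, "grade")
  expect_equal(nrow(out$cohort$subjects), 3)
  expect_equal(out$log$rules$modified[out$log$rules$rule == "missing_grade"],
               2)
  both <- select_complete_cases(co, c("grade", "size"))
  expect_equal(nrow(both$cohort$subjects), 3)
  expect_equal(both$log$rules$removed[both$log$rules$rule ==
                                        "incomplete_case"], 2)
  expect_identical(select_complete_cases(co, character(0))$cohort, co)
  co2 <- co
  co2$subjects$grade <- "missing"
  expect_warning(select_complete_cases(co2, "grade"), "every subject")
  expect_error(select_complete_cases(co, "nope"), "unknown covariate")
})

test_that("the full preparation pipeline preserves invariants on random fixtures", {
  # eligibility -> unconfirmed -> imputation -> truncation on randomized
  # cohorts with all preparation artifacts switched on
  scn <- scenario_preset("smoke")
  for (seed in 1:5) {
    co <- simulate_cohort(scn, seed)
    prep <- prepare_cohort(co, horizon = 8)
    for (lg in prep$logs)
      expect_equal(lg$input_n - sum(lg$rules$removed), lg$output_n)
    expect_s3_class(validate_cohort(prep$cohort), "jf_cohort")
    expect_true(all(prep$cohort$subjects$terminal_time <= 8))
    expect_false(any(prep$cohort$subjects$in_situ))
    expect_true(all(prep$cohort$events$confirmed))
    expect_false(any(prep$cohort$subjects$mets_at_death_only))
  }
})

test_that("cohort summaries match hand enumeration", {
  s <- rbind(subj_row("a", 9), subj_row("b", 8, "death"),
             subj_row("c", 10))
  e <- rbind(event_row("b", 3.8, "locoregional"),
             event_row("c", 2, "metastasis"),
             event_row("c", 6, "second_primary"))
  sm <- summarize_cohort(new_cohort(s, e))
  expect_equal(sm$by_count$n_women, c(1L, 1L, 1L, 0L))
  expect_equal(sm$by_count$median[sm$by_count$n_recurrences == "1"], 3.8)
  expect_equal(sm$by_type$n_events[sm$by_type$type == "metastasis"], 1L)
  expect_equal(sm$deaths$n_deaths, 1L)
  expect_equal(sm$deaths$median, 8)
  # single subject, gaps 2, 4, 6 -> median inter-event gap 4
  s1 <- subj_row("z", 13)
  e1 <- rbind(event_row("z", 2), event_row("z", 6), event_row("z", 12))
  sm1 <- summarize_cohort(new_cohort(s1, e1))
  gaps <- sm1$gaps[sm1$gaps$end_type %in%
    c("locoregional", "metastasis", "second_primary"), ]
  expect_equal(sort(gaps$mean), c(2, 4, 6))
  # medians lie inside their IQRs
  ok <- with(sm$by_type[!is.na(sm$by_type$median), ],
             all(median >= q1 & median <= q3))
  expect_true(ok)
  # empty cohort
  sm0 <- summarize_cohort(new_cohort(subj_row(character(0), numeric(0)),
                                     empty_events()))
  expect_equal(sum(sm0$by_count$n_women), 0L)
})

test_that("cohort CSV and schema round-trip preserves the data", {
  scn <- scenario_preset("smoke")
  co <- simulate_cohort(scn, 3)
  f <- tempfile(fileext = ".csv")
  fs <- tempfile(fileext = ".yaml")
  write_cohort(co, f)
  write_schema(co, fs)
  back <- read_cohort(f, fs)
  expect_equal(back$subjects$terminal_time, co$subjects$terminal_time)
  expect_equal(back$subjects$terminal_status, co$subjects$terminal_status)
  expect_equal(nrow(back$events), nrow(co$events))
  expect_equal(back$codebook, co$codebook)
  expect_equal(back$subjects$group, co$subjects$group)
})
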