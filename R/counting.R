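#' Design specification for the two submodels
#'
#' Declares which covariates enter the recurrence and the death submodel
#' (the two sets may differ) and how categories are reference-coded: for
#' each covariate the codebook's first level is the reference, and every
#' other level gets an indicator column named `"var=level"`.
#'
#' @param codebook named list of category levels (reference first), as
#'   stored in a `jf_cohort`.
#' @param recurrent character vector of covariate names for the
#'   recurrence submodel (may be empty).
#' @param death character vector of covariate names for the death
#'   submodel (may be empty).
#' @return an object of class `jf_design`.
#' @export
make_design <- function(codebook, recurrent = character(), death = character()) {
  unknown <- setdiff(c(recurrent, death), names(codebook))
  if (length(unknown))
    stop("covariate(s) not in codebook: ", paste(unknown, collapse = ", "))
  structure(list(recurrent = recurrent, death = death, codebook = codebook),
            class = "jf_design")
}

# Indicator design matrix for covariate categories held in `data`
# (data.frame of character columns), for the given submodel.
design_matrix <- function(design, data, which = c("recurrent", "death")) {
  which <- match.arg(which)
  vars <- design[[which]]
  cols <- list()
  for (v in vars) {
    lv <- design$codebook[[v]]
    bad <- !data[[v]] %in% lv
    if (any(bad))
      stop("category '", data[[v]][bad][1], "' of covariate '", v,
           "' is not in the codebook (complete cases required)")
    for (l in lv[-1]) cols[[paste0(v, "=", l)]] <- as.numeric(data[[v]] == l)
  }
  if (!length(cols))
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  do.call(cbind, cols)
}

#' Counting-process representation of a cohort
#'
#' Expands each subject into contiguous at-risk intervals on the calendar
#' timescale (years since diagnosis): one half-open interval
#' `(t_start, t_stop]` per inter-event gap, ending with a recurrence
#' indicator, plus a final interval ending at the terminal time carrying
#' the death indicator.  A recurrence tied with the terminal time is kept
#' and the terminal time is perturbed by +1e-9 years (ties logged in the
#' `ties_adjusted` attribute).  Baseline covariates are reference-coded
#' once per subject.
#'
#' @param cohort a prepared `jf_cohort` (complete cases on the modeled
#'   covariates).
#' @param design a `jf_design`.
#' @return an object of class `jf_counting` with elements `rows`
#'   (interval-level data.frame), `subjects` (per-subject `T`, `delta`,
#'   `J`), `XR`, `XD` (per-subject design matrices), `ev_t`/`ev_i`
#'   (recurrence times and subject indices) and `design`.
#' @export
build_counting_process <- function(cohort, design) {
  stopifnot(inherits(cohort, "jf_cohort"), inherits(design, "jf_design"))
  s <- cohort$subjects
  n <- nrow(s)
  ties <- 0L
  Tt <- s$terminal_time
  delta <- as.integer(s$terminal_status == "death")
  ev_by <- split(cohort$events$time, cohort$events$subject_id)
  rows <- vector("list", n)
  J <- integer(n)
  ev_t <- numeric(0); ev_i <- integer(0)
  for (i in seq_len(n)) {
    tt <- ev_by[[s$subject_id[i]]] %||% numeric(0)
    if (length(tt) && max(tt) >= Tt[i] - 1e-12) {
      Tt[i] <- max(tt) + 1e-9
      ties <- ties + 1L
    }
    J[i] <- length(tt)
    starts <- c(0, tt)
    stops <- c(tt, Tt[i])
    rows[[i]] <- data.frame(
      subject_id = s$subject_id[i], t_start = starts, t_stop = stops,
      recurrence = c(rep(1L, length(tt)), 0L),
      terminal = c(rep(0L, length(tt)), delta[i]),
      stringsAsFactors = FALSE)
    if (length(tt)) {
      ev_t <- c(ev_t, tt)
      ev_i <- c(ev_i, rep(i, length(tt)))
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  XR <- design_matrix(design, s, "recurrent")
  XD <- design_matrix(design, s, "death")
  structure(list(rows = rows,
                 subjects = data.frame(subject_id = s$subject_id, T = Tt,
                                       delta = delta, J = J,
                                       stringsAsFactors = FALSE),
                 XR = XR, XD = XD, ev_t = ev_t, ev_i = ev_i,
                 design = design, n = n, ties_adjusted = ties),
            class = "jf_counting")
}

#' Extract one subject's likelihood inputs
#'
#' @param counting a `jf_counting`.
#' @param subject_id a subject identifier present in `counting`.
#' @return list with `J`, `delta`, `T`, `event_times`, `x_R`, `x_D`.
#' @export
subject_slice <- function(counting, subject_id) {
  stopifnot(inherits(counting, "jf_counting"))
  i <- match(subject_id, counting$subjects$subject_id)
  if (is.na(i)) stop("unknown subject ", subject_id)
  list(J = counting$subjects$J[i], delta = counting$subjects$delta[i],
       T = counting$subjects$T[i],
       event_times = counting$ev_t[counting$ev_i == i],
       x_R = counting$XR[i, ], x_D = counting$XD[i, ])
}

# Reconstruct (J, T, delta) per subject from interval rows; used by the
# round-trip invariant tests.
counting_to_summary <- function(counting) {
  r <- counting$rows
  agg <- do.call(rbind, lapply(split(r, r$subject_id), function(g) {
    data.frame(subject_id = g$subject_id[1], T = max(g$t_stop),
               delta = max(g$terminal), J = sum(g$recurrence),
               stringsAsFactors = FALSE)
  }))
  agg[match(counting$subjects$subject_id, agg$subject_id), ]
}

#' @export
print.jf_counting <- function(x, ...) {
  cat(sprintf(paste0("jf_counting: %d subjects, %d intervals, ",
                     "%d recurrences, %d deaths\n"),
              x$n, nrow(x$rows), sum(x$subjects$J), sum(x$subjects$delta)))
  invisible(x)
}
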