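#' Supply diaries and the 182-day gap discontinuation endpoint
#'
#' A diary is the per-subject timeline of days on which tamoxifen was
#' available, built from dispensing records with carry-over of unused supply,
#' and truncated at the earliest censoring event. Early discontinuation is a
#' run of at least `gap_days` consecutive uncovered days within the observed
#' window; the event date is the `gap_days`-th consecutive uncovered day.
#'
#' Conventions: days are integers with day 0 = diagnosis; a supply dispensed
#' on day `d` with `s` days supplied covers days `d, ..., d + s - 1`
#' (half-open interval `[d, d + s)`).
#'
#' @name supply_diary
NULL

# censoring causes in tie-breaking precedence order
.censor_causes <- c("death", "recurrence", "ai_switch", "emigration", "five_years")

# window end and its cause for one subject's event record
censor_window <- function(events_row) {
  days <- c(death = events_row$death_day,
            recurrence = events_row$recurrence_day,
            ai_switch = events_row$ai_switch_day,
            emigration = events_row$emigration_day,
            five_years = events_row$admin_censor_day)
  days <- unlist(days)
  ok <- !is.na(days)
  wend <- min(days[ok])
  # precedence on ties: death > recurrence > ai_switch > emigration > five_years
  cause <- .censor_causes[.censor_causes %in% names(days)[ok & days == wend]][1L]
  list(window_end = as.integer(wend), cause = cause)
}

# vectorized window end + cause for a whole event table
censor_window_cohort <- function(events) {
  m <- cbind(death = events$death_day, recurrence = events$recurrence_day,
             ai_switch = events$ai_switch_day,
             emigration = events$emigration_day,
             five_years = events$admin_censor_day)
  wend <- suppressWarnings(apply(m, 1, min, na.rm = TRUE))
  cause <- rep("five_years", nrow(m))
  for (cz in rev(.censor_causes)) {
    hit <- !is.na(m[, cz]) & m[, cz] == wend
    cause[hit] <- cz
  }
  list(window_end = as.integer(wend), cause = cause)
}

# coverage intervals (matrix [start, end)) from sorted dispensings with
# carry-over of the capped remainder, truncated to [init, wend).
# Held stock is state: at each dispensing the remainder is capped -- excess
# beyond the cap is forfeited -- so a refill can shorten previously projected
# coverage.
coverage_core <- function(d, s, init, wend, cap) {
  cov <- matrix(numeric(0), ncol = 2)
  stock_end <- -Inf
  for (i in seq_along(d)) {
    carry <- min(max(0, stock_end - d[i]), cap)
    new_end <- d[i] + s[i] + carry
    if (nrow(cov) > 0 && d[i] <= cov[nrow(cov), 2]) {
      cov[nrow(cov), 2] <- new_end
    } else {
      cov <- rbind(cov, c(d[i], new_end))
    }
    stock_end <- new_end
  }
  if (nrow(cov) > 0) {
    cov[, 1] <- pmax(cov[, 1], init)
    cov[, 2] <- pmin(cov[, 2], wend)
    cov <- cov[cov[, 2] > cov[, 1], , drop = FALSE]
  }
  cov
}

# first gap of >= gap_days uncovered days in [init, wend); returns the event
# day (the gap_days-th uncovered day) or NA
gap_event_day <- function(cov, init, wend, gap_days) {
  if (nrow(cov) == 0) {
    starts <- init
    ends <- wend
  } else {
    starts <- c(init, cov[, 2])
    ends <- c(cov[, 1], wend)
  }
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  hit <- which(ends - starts >= gap_days)
  if (length(hit)) as.integer(starts[hit[1L]] + gap_days - 1L) else NA_integer_
}

#' Build a coverage diary from dispensing records
#'
#' On each resupply, any remaining coverage from the previous supply -- capped
#' at `carryover_cap_days` -- is carried over and added to the new supply.
#' Coverage is truncated at the window end (earliest censoring event).
#' Dispensings on or after the window end are dropped with a warning.
#'
#' @param supplies Data frame with `dispense_day` and `days_supplied` for one
#'   subject, sorted by `dispense_day`.
#' @param events One-row data frame (or list) with the subject's censoring
#'   days: `ai_switch_day`, `recurrence_day`, `death_day`, `emigration_day`
#'   (NA where absent) and `admin_censor_day`.
#' @param initiation_day Day of tamoxifen initiation.
#' @param carryover_cap_days Cap on the carried remainder (default 182).
#' @return A list of class `diary`: `coverage` (two-column matrix of
#'   half-open [start, end) intervals), `window_end`, `censor_cause`,
#'   `initiation_day`.
#' @export
build_diary <- function(supplies, events, initiation_day,
                        carryover_cap_days = 182) {
  cw <- censor_window(events)
  d <- supplies$dispense_day
  s <- supplies$days_supplied
  if (is.unsorted(d)) stop("supplies out of order")
  keep <- d < cw$window_end
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " dispensing(s) on/after window end")
    d <- d[keep]; s <- s[keep]
  }
  structure(list(coverage = coverage_core(d, s, initiation_day,
                                          cw$window_end, carryover_cap_days),
                 window_end = cw$window_end, censor_cause = cw$cause,
                 initiation_day = as.integer(initiation_day)),
            class = "diary")
}

#' Derive the discontinuation outcome from a diary
#'
#' Scans uncovered days in `[initiation_day, window_end)`. The first run
#' reaching `gap_days` consecutive uncovered days triggers the event, dated
#' at the run's `gap_days`-th day; a run cut short by the window end does not
#' count (the event requires `gap_days` observed uncovered days).
#'
#' @param diary A `diary` from [build_diary()].
#' @param gap_days Gap threshold in days (default 182).
#' @return Data frame row: `time_days` (from initiation), `event` (1 =
#'   discontinued, 0 = censored), `censor_reason` (`none` for events).
#' @export
derive_outcome <- function(diary, gap_days = 182) {
  ed <- gap_event_day(diary$coverage, diary$initiation_day, diary$window_end,
                      gap_days)
  if (!is.na(ed) && ed < diary$window_end) {
    data.frame(time_days = ed - diary$initiation_day, event = 1L,
               censor_reason = "none", stringsAsFactors = FALSE)
  } else {
    data.frame(time_days = as.integer(diary$window_end - diary$initiation_day),
               event = 0L, censor_reason = diary$censor_cause,
               stringsAsFactors = FALSE)
  }
}

#' Derive discontinuation outcomes for a whole cohort
#'
#' @param supplies Cohort supply table (`subject_id`, `dispense_day`,
#'   `days_supplied`).
#' @param events Cohort event table (one row per subject).
#' @param initiations Data frame with `subject_id` and `initiation_day`
#'   (e.g. the covariate table).
#' @param gap_days Gap threshold (default 182).
#' @param carryover_cap_days Carry-over cap (default 182).
#' @param verbose Log the event count and censor-reason tally.
#' @return Data frame: `subject_id`, `time_days`, `event`, `censor_reason`.
#' @export
derive_cohort_outcomes <- function(supplies, events, initiations,
                                   gap_days = 182, carryover_cap_days = 182,
                                   verbose = FALSE) {
  ids <- initiations$subject_id
  n <- length(ids)
  if (n == 0L) {
    return(data.frame(subject_id = character(), time_days = integer(),
                      event = integer(), censor_reason = character(),
                      stringsAsFactors = FALSE))
  }
  miss <- setdiff(ids, events$subject_id)
  if (length(miss)) stop("subject missing from events: ", miss[1L])
  ev_idx <- match(ids, events$subject_id)
  cw <- censor_window_cohort(events[ev_idx, , drop = FALSE])
  sidx <- split(seq_len(nrow(supplies)),
                factor(supplies$subject_id, levels = ids))
  disp <- supplies$dispense_day
  supl <- supplies$days_supplied
  init <- initiations$initiation_day

  time_days <- integer(n)
  event <- integer(n)
  reason <- character(n)
  dropped <- 0L
  for (i in seq_len(n)) {
    j <- sidx[[i]]
    d <- disp[j]; s <- supl[j]
    if (is.unsorted(d)) {
      o <- order(d); d <- d[o]; s <- s[o]
    }
    keep <- d < cw$window_end[i]
    dropped <- dropped + sum(!keep)
    cov <- coverage_core(d[keep], s[keep], init[i], cw$window_end[i],
                         carryover_cap_days)
    ed <- gap_event_day(cov, init[i], cw$window_end[i], gap_days)
    if (!is.na(ed)) {
      time_days[i] <- ed - init[i]
      event[i] <- 1L
      reason[i] <- "none"
    } else {
      time_days[i] <- cw$window_end[i] - init[i]
      reason[i] <- cw$cause[i]
    }
  }
  if (dropped > 0L) {
    warning("dropped ", dropped, " dispensing(s) on/after the censoring window")
  }
  res <- data.frame(subject_id = ids, time_days = time_days, event = event,
                    censor_reason = reason, stringsAsFactors = FALSE)
  if (verbose) {
    tally <- table(factor(res$censor_reason, levels = c("none", .censor_causes)))
    message(sprintf("outcomes: %d subjects, %d events; censoring: %s",
                    nrow(res), sum(res$event),
                    paste(names(tally), tally, sep = "=", collapse = " ")))
  }
  res
}
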