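no_censor <- function(...) {
  ev <- data.frame(ai_switch_day = NA_integer_, recurrence_day = NA_integer_,
                   death_day = NA_integer_, emigration_day = NA_integer_,
                   admin_censor_day = 1825L)
  mod <- list(...)
  for (nm in names(mod)) ev[[nm]] <- mod[[nm]]
  ev
}

test_that("carry-over and truncation rules produce the documented coverage", {
  # resupply before exhaustion: 92 remaining days carried onto the new supply
  d <- build_diary(data.frame(dispense_day = c(0, 90), days_supplied = 182),
                   no_censor(), 0)
  expect_equal(d$coverage, cbind(0, 364), ignore_attr = TRUE)
  # exhausted supply: no carry-over, a genuine gap remains
  d2 <- build_diary(data.frame(dispense_day = c(0, 300), days_supplied = 182),
                    no_censor(), 0)
  expect_equal(d2$coverage, rbind(c(0, 182), c(300, 482)), ignore_attr = TRUE)
  # censoring truncates coverage and sets the window end
  d3 <- build_diary(data.frame(dispense_day = 0, days_supplied = 182),
                    no_censor(ai_switch_day = 100L), 0)
  expect_equal(d3$coverage, cbind(0, 100), ignore_attr = TRUE)
  expect_equal(d3$window_end, 100L)
  expect_equal(d3$censor_cause, "ai_switch")
  # carried remainder is capped, the new supply counts fully
  d4 <- build_diary(data.frame(dispense_day = c(0, 90, 180), days_supplied = 182),
                    no_censor(), 0, carryover_cap_days = 182)
  expect_equal(max(d4$coverage[, 2]), 180 + 182 + 182)
  expect_error(build_diary(data.frame(dispense_day = c(100, 0),
                                      days_supplied = 182), no_censor(), 0),
               "out of order")
  expect_warning(build_diary(data.frame(dispense_day = c(0, 200),
                                        days_supplied = 182),
                             no_censor(ai_switch_day = 100L), 0),
                 "dropping")
})

test_that("the gap rule dates events at the 182nd uncovered day", {
  d1 <- build_diary(data.frame(dispense_day = c(0, 90), days_supplied = 182),
                    no_censor(), 0)
  expect_equal(derive_outcome(d1),
               data.frame(time_days = 545L, event = 1L, censor_reason = "none"))
  d2 <- build_diary(data.frame(dispense_day = c(0, 300), days_supplied = 182),
                    no_censor(), 0)
  # interior 118-day gap does not trigger; the post-482 gap does
  expect_equal(derive_outcome(d2)$time_days, 663L)
  d3 <- build_diary(data.frame(dispense_day = 0, days_supplied = 182),
                    no_censor(recurrence_day = 250L), 0)
  expect_equal(derive_outcome(d3),
               data.frame(time_days = 250L, event = 0L,
                          censor_reason = "recurrence"))
})

test_that("tied censoring days resolve by the documented precedence", {
  ev <- no_censor(death_day = 500L, recurrence_day = 500L, ai_switch_day = 500L)
  d <- build_diary(data.frame(dispense_day = 0, days_supplied = 182), ev, 0)
  expect_equal(d$censor_cause, "death")
  ev2 <- no_censor(recurrence_day = 500L, ai_switch_day = 500L)
  expect_equal(build_diary(data.frame(dispense_day = 0, days_supplied = 182),
                           ev2, 0)$censor_cause, "recurrence")
})

test_that("cohort outcomes compose per-subject results and conserve counts", {
  sup <- rbind(
    data.frame(subject_id = "s1", dispense_day = c(0, 90), days_supplied = 182),
    data.frame(subject_id = "s2", dispense_day = c(0, 300), days_supplied = 182),
    data.frame(subject_id = "s3", dispense_day = 0, days_supplied = 182))
  ev <- data.frame(subject_id = c("s1", "s2", "s3"),
                   ai_switch_day = NA_integer_,
                   recurrence_day = c(NA, NA, 250L),
                   death_day = NA_integer_, emigration_day = NA_integer_,
                   admin_censor_day = 1825L)
  init <- data.frame(subject_id = c("s1", "s2", "s3"), initiation_day = 0L)
  oc <- derive_cohort_outcomes(sup, ev, init)
  expect_equal(oc$event, c(1L, 1L, 0L))
  expect_equal(oc$time_days, c(545L, 663L, 250L))
  expect_equal(nrow(oc), 3L)
  expect_equal(sum(oc$event) + sum(oc$censor_reason != "none"), 3L)
  # empty cohort
  empty <- derive_cohort_outcomes(sup[0, ], ev[0, ],
                                  init[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
  expect_error(derive_cohort_outcomes(sup, ev[-1, ], init), "missing")
})

test_that("adding a dispensing or raising the gap threshold is monotone", {
  set.seed(42)
  for (i in 1:60) {
    fx <- random_diary_fixture()
    dfix <- suppressWarnings(build_diary(fx$supplies, fx$events,
                                         fx$initiation_day))
    base <- derive_outcome(dfix)
    # add one full-length dispensing
    extra_day <- fx$initiation_day + sample(1:1700, 1)
    sup2 <- fx$supplies
    if (!extra_day %in% sup2$dispense_day) {
      sup2 <- rbind(sup2, data.frame(dispense_day = extra_day,
                                     days_supplied = 182L))
      sup2 <- sup2[order(sup2$dispense_day), ]
      more <- derive_outcome(suppressWarnings(
        build_diary(sup2, fx$events, fx$initiation_day)))
      expect_gte(more$time_days, base$time_days)
      expect_true(!(base$event == 0 && more$event == 1))
    }
    # raise the gap threshold
    wider <- derive_outcome(dfix, gap_days = 365)
    expect_lte(wider$event, base$event)
  }
})

test_that("interval engine equals the day-by-day brute force on random fixtures", {
  set.seed(99)
  for (i in 1:250) {
    fx <- random_diary_fixture()
    a <- suppressWarnings(
      derive_outcome(build_diary(fx$supplies, fx$events, fx$initiation_day)))
    b <- brute_force_outcome(fx$supplies, fx$events, fx$initiation_day)
    expect_identical(a$event, b$event)
    expect_identical(a$time_days, b$time_days)
    expect_identical(a$censor_reason, b$censor_reason)
  }
})
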