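test_that("action windows follow the 5-hour rule", {
  a <- scheduled_action("p1", "medication_intake", ts_utc("2026-01-05 08:00:00"),
                        drug = "beta_blocker")
  expect_equal(as.numeric(a$window_close - a$window_open, units = "hours"), 5)
  expect_equal(a$window_open, ts_utc("2026-01-05 07:00:00"))
  expect_equal(a$reminder_at, ts_utc("2026-01-05 10:00:00"))
  expect_equal(a$window_close, ts_utc("2026-01-05 12:00:00"))
  expect_error(scheduled_action("p1", "medication_intake",
                                ts_utc("2026-01-05 08:00:00")), "drug")
})

test_that("early in-window confirmation resolves with no reminder", {
  a <- scheduled_action("p1", "medication_intake", ts_utc("2026-01-05 08:00:00"),
                        drug = "ace_i")
  r <- lifecycle(a, tibble::tibble(time = ts_utc("2026-01-05 07:30:00"),
                                   channel = "app", response = "confirm"))
  expect_equal(r$ledger$outcome, "confirmed_app")
  expect_equal(r$ledger$resolved_at, ts_utc("2026-01-05 07:30:00"))
  expect_equal(nrow(r$events), 0L)
  expect_null(r$call)
})

test_that("late in-window confirmation still gets the reminder first", {
  a <- scheduled_action("p1", "medication_intake", ts_utc("2026-01-05 08:00:00"),
                        drug = "ace_i")
  r <- lifecycle(a, tibble::tibble(time = ts_utc("2026-01-05 11:00:00"),
                                   channel = "app", response = "confirm"))
  expect_equal(r$ledger$outcome, "confirmed_app")
  expect_equal(r$events$type, "reminder")
  expect_equal(r$events$time, a$reminder_at)
})

test_that("duplicate and out-of-window responses: first in-window wins", {
  a <- scheduled_action("p1", "medication_intake", ts_utc("2026-01-05 08:00:00"),
                        drug = "ace_i")
  resp <- tibble::tibble(
    time = ts_utc(c("2026-01-05 06:00:00", "2026-01-05 07:10:00",
                    "2026-01-05 09:00:00")),
    channel = "app", response = c("confirm", "decline", "confirm"))
  r <- lifecycle(a, resp)
  expect_equal(r$ledger$outcome, "declined_app")  # 06:00 is before the window
  expect_equal(r$ledger$resolved_at, ts_utc("2026-01-05 07:10:00"))
})

test_that("no response escalates: reminder, tag, call, phone outcome", {
  a <- scheduled_action("p1", "medication_intake", ts_utc("2026-01-05 08:00:00"),
                        drug = "diuretic")
  r <- lifecycle(a, tibble::tibble(time = ts_utc("2026-01-05 13:10:00"),
                                   channel = "call", response = "confirm"))
  expect_equal(r$events$type, c("reminder", "no_registration_tag"))
  expect_equal(r$events$time, c(ts_utc("2026-01-05 10:00:00"),
                                ts_utc("2026-01-05 12:00:00")))
  expect_equal(r$call$reason, "missed_medication")
  expect_equal(r$call$placed_at, ts_utc("2026-01-05 13:10:00"))
  expect_equal(r$ledger$outcome, "confirmed_callcenter")
})

test_that("weekend escalation defers the call to Monday working hours", {
  sat <- ts_utc("2026-01-10 08:00:00")  # Saturday
  a <- scheduled_action("p1", "vital_measurement", sat)
  cal <- work_calendar()
  r <- lifecycle(a, NULL, cal, unanswered = "confirm")
  expect_equal(r$events$time[r$events$type == "no_registration_tag"],
               ts_utc("2026-01-10 12:00:00"))
  expect_equal(r$call$placed_at, ts_utc("2026-01-12 08:00:00"))
  expect_true(is_working_time(cal, r$call$placed_at))
  expect_equal(r$call$placed_at, next_working_time(cal, a$window_close))
})

test_that("no_recording is reserved for vitals and questionnaires", {
  a_vit <- scheduled_action("p1", "vital_measurement", ts_utc("2026-01-05 08:00:00"))
  r <- lifecycle(a_vit, NULL, unanswered = "none")
  expect_equal(r$ledger$outcome, "no_recording")
  a_med <- scheduled_action("p1", "medication_intake", ts_utc("2026-01-05 08:00:00"),
                            drug = "ace_i")
  expect_error(lifecycle(a_med, NULL, unanswered = "none"),
               "vitals and questionnaires")
})

test_that("reminder < tag < call ordering holds for any unresolved action", {
  set.seed(11)
  cal <- work_calendar()
  for (i in 1:20) {
    day <- d0 + sample(0:27, 1)
    hour <- sample(6:20, 1)
    a <- scheduled_action("p1", "vital_measurement",
                          ts_utc(sprintf("%s %02d:00:00", format(day), hour)))
    r <- lifecycle(a, NULL, cal, unanswered = "none")
    tr <- r$events$time[r$events$type == "reminder"]
    tt <- r$events$time[r$events$type == "no_registration_tag"]
    expect_true(tr < tt)
    expect_true(tt <= r$call$placed_at)
    expect_true(is_working_time(cal, r$call$placed_at))
  }
})

test_that("every action resolves to exactly one terminal ledger entry", {
  set.seed(12)
  cal <- work_calendar()
  n <- 0L
  ledgers <- list()
  for (i in 1:50) {
    a <- scheduled_action("p1", sample(c("medication_intake", "vital_measurement",
                                         "questionnaire"), 1),
                          ts_utc(sprintf("%s 08:00:00", format(d0 + i))),
                          drug = "beta_blocker")
    resp <- if (stats::runif(1) < 0.5) {
      tibble::tibble(time = a$ideal_time + stats::runif(1, -3600, 4 * 3600),
                     channel = "app",
                     response = sample(c("confirm", "decline"), 1))
    } else NULL
    r <- lifecycle(a, resp, cal,
                   unanswered = if (a$kind == "medication_intake") "decline" else "none")
    n <- n + 1L
    ledgers[[i]] <- r$ledger
  }
  led <- do.call(rbind, ledgers)
  expect_equal(nrow(led), n)
  expect_true(all(led$outcome %in% c("confirmed_app", "confirmed_callcenter",
                                     "declined_app", "declined_callcenter",
                                     "no_recording")))
  rep <- compute_adherence(led)
  expect_equal(rep$overall$total, n)
  outcome_cols <- c("confirmed_app", "confirmed_callcenter", "declined_app",
                    "declined_callcenter", "no_recording")
  expect_equal(sum(unlist(rep$overall[outcome_cols])), n)
})

test_that("adherence percentage is confirmed/total at 2 decimals half-up", {
  led <- ledger_from_counts(c(confirmed_app = 8315, confirmed_callcenter = 1703,
                              declined_app = 351, declined_callcenter = 456))
  rep <- compute_adherence(led)
  expect_equal(rep$overall$total, 10825L)
  expect_equal(rep$overall$n_adherent, 10018L)
  expect_equal(rep$overall$adherence_pct, 92.55)

  all_conf <- ledger_from_counts(c(confirmed_app = 120))
  expect_equal(compute_adherence(all_conf)$overall$adherence_pct, 100.00)
})

test_that("vitals adherence separates phone recoveries from no recording", {
  led <- ledger_from_counts(c(confirmed_app = 3902, confirmed_callcenter = 602,
                              no_recording = 254), kind = "vital_measurement")
  rep <- compute_adherence(led)
  expect_equal(rep$overall$adherence_pct, 94.66)
  expect_equal(round_half_up(100 * rep$overall$no_recording /
                               rep$overall$total, 2), 5.34)
})

test_that("empty ledger yields a defined report without division", {
  rep <- compute_adherence(ledger_from_counts(integer(0))[0, ])
  expect_equal(rep$overall$total, 0L)
  expect_true(is.na(rep$overall$adherence_pct))
})

test_that("call statistics use interpolated quartiles", {
  calls <- tibble::tibble(patient_id = rep(c("a", "b", "c"), c(2, 4, 6)),
                          reason = "missed_vitals")
  st <- call_center_stats(calls)
  expect_equal(st$total, 12L)
  expect_equal(st$median, 4)
  expect_equal(st$q1, 3)
  expect_equal(st$q3, 5)

  one <- tibble::tibble(patient_id = rep("a", 5), reason = "technical")
  st1 <- call_center_stats(one)
  expect_equal(st1$median, 5)
  expect_equal(c(st1$q1, st1$q3), c(5, 5))
})

test_that("per-reason counts sum to the call total", {
  calls <- tibble::tibble(
    patient_id = sample(letters[1:5], 40, replace = TRUE),
    reason = sample(c("missed_medication", "missed_vitals",
                      "missed_questionnaire"), 40, replace = TRUE))
  st <- call_center_stats(calls)
  expect_equal(sum(st$by_reason), st$total)
  expect_equal(sum(st$per_patient), st$total)
})
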