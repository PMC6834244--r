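#' A scheduled patient action
#'
#' One required daily action: a medication intake confirmation, a vital
#' sign measurement, or a questionnaire. Each action has a 5-hour
#' completion window opening one hour before the ideal time and closing
#' four hours after it; an app reminder fires two hours after the ideal
#' time if the action is still open.
#'
#' @param patient_id patient identifier.
#' @param kind `"medication_intake"`, `"vital_measurement"` or
#'   `"questionnaire"`.
#' @param ideal_time `POSIXct` ideal completion instant.
#' @param drug for medication intakes: `"beta_blocker"`, `"ace_i"` or
#'   `"diuretic"`; `NA` otherwise.
#' @return a one-row tibble with window columns computed.
#' @export
#' @examples
#' scheduled_action("p1", "medication_intake",
#'                  as.POSIXct("2026-01-05 08:00", tz = "UTC"),
#'                  drug = "beta_blocker")
scheduled_action <- function(patient_id,
                             kind = c("medication_intake", "vital_measurement",
                                      "questionnaire"),
                             ideal_time, drug = NA_character_) {
  kind <- match.arg(kind)
  if (kind == "medication_intake") {
    assert_that(drug %in% c("beta_blocker", "ace_i", "diuretic"),
                "medication_intake requires drug beta_blocker/ace_i/diuretic")
  } else {
    drug <- NA_character_
  }
  assert_that(inherits(ideal_time, "POSIXct") && length(ideal_time) == 1,
              "ideal_time must be a scalar POSIXct")
  fast_row(
    patient_id = as.character(patient_id), kind = kind, drug = drug,
    ideal_time = ideal_time,
    window_open = ideal_time - 3600,
    reminder_at = ideal_time + 2 * 3600,
    window_close = ideal_time + 4 * 3600
  )
}

terminal_outcomes <- c("confirmed_app", "confirmed_callcenter",
                       "declined_app", "declined_callcenter", "no_recording")

reason_for_kind <- c(medication_intake = "missed_medication",
                     vital_measurement = "missed_vitals",
                     questionnaire = "missed_questionnaire")

#' Run the lifecycle of one scheduled action
#'
#' Resolves a scheduled action to exactly one terminal ledger outcome and
#' returns the events emitted along the way:
#' * an app confirmation or explicit decline inside the window resolves
#'   the action immediately (`confirmed_app` / `declined_app`); the first
#'   in-window response wins and later responses are ignored;
#' * if still open two hours after the ideal time, one reminder is pushed;
#' * if still open when the window closes, a *no-registration* tag is
#'   recorded and a technical call-center task becomes due (within 12
#'   hours of window close, deferred to the next working instant when the
#'   calendar is closed); the call resolves the action to
#'   `confirmed_callcenter`, `declined_callcenter`, or — for vital
#'   measurements and questionnaires only — `no_recording`.
#'
#' @param action a [scheduled_action()].
#' @param responses tibble of time-ordered patient responses with columns
#'   `time` (`POSIXct`), `channel` (`"app"` or `"call"`) and `response`
#'   (`"confirm"`, `"decline"` or `"none"`). App responses outside the
#'   window are ignored. A `call` row, if present, records what the
#'   patient reported when phoned and when the call took place.
#' @param calendar a [work_calendar()] governing when calls can be placed.
#' @param unanswered for escalated actions with no `call` row: what the
#'   placed call established. Defaults to `"none"` (no recording could be
#'   obtained) for vitals/questionnaires and `"decline"` for medication
#'   intakes, where "no recording" is not a permitted ledger category.
#' @return a list with elements `ledger` (one-row tibble: action fields
#'   plus `outcome`, `resolved_at`), `events` (tibble of emitted
#'   `reminder` / `no_registration_tag` events) and `call` (one-row
#'   tibble of the placed call, or `NULL`).
#' @export
lifecycle <- function(action, responses = NULL, calendar = work_calendar(),
                      unanswered = NULL) {
  if (is.null(responses)) {
    responses <- tibble::tibble(time = as.POSIXct(character(), tz = "UTC"),
                                channel = character(), response = character())
  }
  assert_that(!is.unsorted(responses$time),
              "responses must be time-ordered")
  events <- list()
  emit <- function(type, time) {
    events[[length(events) + 1L]] <<- fast_row(
      type = type, patient_id = action$patient_id, kind = action$kind,
      drug = action$drug, time = time)
  }
  app <- responses[responses$channel == "app" &
                     responses$time >= action$window_open &
                     responses$time <= action$window_close &
                     responses$response %in% c("confirm", "decline"), ]
  if (nrow(app) > 0) {
    first <- app[1, ]  # duplicate completion: first wins
    if (first$time > action$reminder_at) emit("reminder", action$reminder_at)
    ledger <- ledger_row(action,
                         outcome = if (first$response == "confirm")
                           "confirmed_app" else "declined_app",
                         resolved_at = first$time)
    return(list(ledger = ledger, events = bind_events(events), call = NULL))
  }
  # unresolved in-window: reminder, then tag + call-center escalation
  emit("reminder", action$reminder_at)
  emit("no_registration_tag", action$window_close)
  due <- action$window_close
  call_rows <- responses[responses$channel == "call" &
                           responses$time >= action$window_close, ]
  if (nrow(call_rows) > 0) {
    placed_at <- call_rows$time[1]
    said <- call_rows$response[1]
  } else {
    placed_at <- next_working_time(calendar, due)
    said <- unanswered %||%
      if (action$kind == "medication_intake") "decline" else "none"
  }
  outcome <- switch(said,
    confirm = "confirmed_callcenter",
    decline = "declined_callcenter",
    none = {
      assert_that(action$kind != "medication_intake",
                  "no_recording applies only to vitals and questionnaires")
      "no_recording"
    },
    stop("unknown call response: ", said, call. = FALSE))
  call <- fast_row(
    patient_id = action$patient_id, placed_at = placed_at,
    reason = unname(reason_for_kind[[action$kind]]),
    kind = action$kind, drug = action$drug)
  ledger <- ledger_row(action, outcome = outcome, resolved_at = placed_at)
  list(ledger = ledger, events = bind_events(events), call = call)
}

ledger_row <- function(action, outcome, resolved_at) {
  fast_row(
    patient_id = action$patient_id, kind = action$kind, drug = action$drug,
    ideal_time = action$ideal_time, outcome = outcome,
    resolved_at = resolved_at)
}

bind_events <- function(events) {
  if (length(events) == 0) {
    return(tibble::tibble(type = character(), patient_id = character(),
                          kind = character(), drug = character(),
                          time = as.POSIXct(character(), tz = "UTC")))
  }
  do.call(rbind, events)
}

#' Adherence accounting over a resolved ledger
#'
#' Tallies terminal outcomes overall, per action kind and per drug, and
#' computes adherence as the share of actions eventually confirmed,
#' whether in the app or over the phone:
#' \deqn{\mathrm{adherence} = \frac{confirmed\_app + confirmed\_callcenter}{total}}
#' Percentages are reported to two decimals with half-up rounding.
#'
#' @param ledger tibble of ledger rows (one per scheduled action) with at
#'   least columns `kind`, `drug`, `outcome`.
#' @return a list of class `adherence_report` with elements `overall`,
#'   `by_kind`, `by_drug`, each a tibble of columns `stratum`, one count
#'   column per outcome, `total`, `n_adherent`, `adherence_pct`.
#' @export
#' @examples
#' led <- tibble::tibble(kind = "medication_intake", drug = "ace_i",
#'                       outcome = rep(c("confirmed_app", "declined_app"),
#'                                     c(9, 1)))
#' compute_adherence(led)$overall
compute_adherence <- function(ledger) {
  strat <- function(rows, stratum) {
    counts <- vapply(terminal_outcomes,
                     function(o) sum(rows$outcome == o), integer(1))
    total <- nrow(rows)
    n_adh <- counts[["confirmed_app"]] + counts[["confirmed_callcenter"]]
    pct <- if (total == 0) NA_real_ else round_half_up(100 * n_adh / total, 2)
    tibble::tibble(stratum = stratum, !!!as.list(counts), total = total,
                   n_adherent = n_adh, adherence_pct = pct)
  }
  by_kind <- do.call(rbind, lapply(
    sort(unique(ledger$kind)), function(k) strat(ledger[ledger$kind == k, ], k)))
  med <- ledger[!is.na(ledger$drug), ]
  by_drug <- do.call(rbind, lapply(
    sort(unique(med$drug)), function(d) strat(med[med$drug == d, ], d)))
  out <- list(overall = strat(ledger, "overall"),
              by_kind = by_kind %||% strat(ledger[0, ], character(0)),
              by_drug = by_drug)
  class(out) <- "adherence_report"
  out
}

#' @export
print.adherence_report <- function(x, ...) {
  cat("<adherence_report>\n overall:\n")
  print(x$overall)
  cat(" by kind:\n")
  print(x$by_kind)
  if (!is.null(x$by_drug) && nrow(x$by_drug) > 0) {
    cat(" by drug:\n")
    print(x$by_drug)
  }
  invisible(x)
}

#' Technical call-center statistics
#'
#' Total calls, per-reason counts, and the per-patient distribution
#' (median and interquartile range of calls per patient). Quartiles use
#' linear interpolation ([stats::quantile()] type 7) so small examples
#' are exactly reproducible.
#'
#' @param calls tibble of placed calls with columns `patient_id`,
#'   `reason`.
#' @return a list with `total`, `by_reason` (named integer vector),
#'   `per_patient` (integer vector of counts), `median`, `q1`, `q3`.
#' @export
call_center_stats <- function(calls) {
  per_patient <- as.integer(table(calls$patient_id))
  by_reason <- if (nrow(calls) > 0) {
    tab <- table(calls$reason)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  if (length(per_patient) == 0) {
    return(list(total = 0L, by_reason = by_reason, per_patient = integer(0),
                median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  qs <- stats::quantile(per_patient, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(total = nrow(calls), by_reason = by_reason, per_patient = per_patient,
       median = qs[2], q1 = qs[1], q3 = qs[3])
}
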