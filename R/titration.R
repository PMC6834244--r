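#' Build the biweekly uptitration proposal schedule
#'
#' During the active uptitration phase (the first ~3 months of
#' follow-up), the engine generates a proposal every 14 days, alternating
#' between the beta-blocker and the ACE-I, starting with the beta-blocker
#' at the beginning of week 2. Each proposal is preceded by a short
#' symptom questionnaire pushed to the patient, and each ACE-I proposal
#' by a blood-withdrawal request for kidney function, issued one week
#' before the proposal. After the active phase no further proposals are
#' generated (monitoring continues in the less intensive phase).
#'
#' With the defaults (91-day active phase, 14-day interval) this yields 6
#' proposals: beta-blocker at days 14, 42, 70 and ACE-I at days 28, 56,
#' 84, with blood requests at days 21, 49 and 77.
#'
#' @param enrollment_date `Date` of enrollment (day 0).
#' @param active_phase_days length of the active uptitration phase in
#'   days; must be at least `first_offset_days`.
#' @param interval_days days between consecutive proposals.
#' @param first_offset_days days from enrollment to the first proposal.
#' @param blood_lead_days days before an ACE-I proposal at which the
#'   blood withdrawal is requested.
#' @return a tibble of proposal events with columns `sequence_index`,
#'   `due_date`, `drug_class`, `questionnaire_due_date`,
#'   `blood_request_date` (`NA` for beta-blocker events) and
#'   `proposal_time` (proposals are generated at 08:00 on the due date).
#' @export
#' @examples
#' build_schedule(as.Date("2026-01-05"))
build_schedule <- function(enrollment_date, active_phase_days = 91,
                           interval_days = 14, first_offset_days = 14,
                           blood_lead_days = 7) {
  enrollment_date <- as_date_scalar(enrollment_date, "enrollment_date")
  assert_that(active_phase_days >= first_offset_days,
              "active phase must contain at least one proposal interval")
  offsets <- seq(first_offset_days, active_phase_days, by = interval_days)
  n <- length(offsets)
  due <- enrollment_date + offsets
  drug_class <- rep(c("beta_blocker", "ace_i"), length.out = n)
  tibble::tibble(
    sequence_index = seq_len(n),
    due_date = due,
    drug_class = drug_class,
    questionnaire_due_date = due,
    blood_request_date = as.Date(ifelse(drug_class == "ace_i",
                                        format(due - blood_lead_days), NA)),
    proposal_time = as.POSIXct(paste(format(due), "08:00:00"), tz = "UTC")
  )
}

proposal_outcomes <- c("UPTITRATE", "NO_UPTITRATION", "NURSE_EVAL_INCOMPLETE",
                       "NURSE_EVAL_ABERRANT_VITALS", "NURSE_EVAL_ABERRANT_BLOOD")

#' Assess the data window preceding a proposal
#'
#' Summarises the 14 days of telemetry before a proposal's due date:
#' the completeness of daily measurements and whether any threshold
#' crossing (or sustained alert) occurred in the window.
#'
#' @param samples tibble of one patient's vital samples (columns as in
#'   [vital_sample()]); rows outside the window are ignored.
#' @param due_date the proposal due date; the window is
#'   `[due_date - window_days, due_date)`.
#' @param baseline_weight enrollment weight in kg.
#' @param thresholds a [threshold_set()].
#' @param window_days window length in days.
#' @param expected_days number of measurement days expected in the
#'   window; defaults to `window_days` (one measurement set per day).
#' @return a list of class `data_quality` with `completeness` (fraction
#'   of expected days with at least one measurement), `aberrant`
#'   (logical), `crossings` (tibble) and `alerts` (tibble).
#' @export
assess_window <- function(samples, due_date, baseline_weight,
                          thresholds = threshold_set(), window_days = 14,
                          expected_days = window_days) {
  due_date <- as_date_scalar(due_date, "due_date")
  assert_that(window_days >= 1, "window must span at least one day")
  win <- samples[samples$date >= due_date - window_days &
                   samples$date < due_date, , drop = FALSE]
  measured_days <- length(unique(win$date))
  completeness <- measured_days / expected_days
  if (nrow(win) > 0) {
    pid <- win$patient_id[[1]]
    crossings <- evaluate_samples(win, stats::setNames(baseline_weight, pid),
                                  thresholds)
    measured <- window_measured(win)
    alerts <- detect_sustained(crossings, measured, thresholds)
  } else {
    crossings <- empty_crossings()
    alerts <- detect_sustained(empty_crossings(), NULL, thresholds)
  }
  structure(list(completeness = completeness,
                 aberrant = nrow(crossings) > 0 || nrow(alerts) > 0,
                 crossings = crossings, alerts = alerts),
            class = "data_quality")
}

# long (date, parameter) table of days on which each vital was measured
window_measured <- function(samples) {
  long <- lapply(vital_parameters, function(p) {
    col <- if (p == "weight") samples$weight
    else if (p == "heart_rate") samples$heart_rate
    else if (p == "systolic") samples$systolic
    else samples$diastolic
    tibble::tibble(date = samples$date[!is.na(col)], parameter = p)
  })
  do.call(rbind, long)
}

#' A pre-proposal symptom report
#'
#' Answers to the short heart-failure questionnaire pushed before each
#' proposal: generic red-flag booleans plus free text.
#'
#' @param patient_id patient identifier.
#' @param date report date.
#' @param dizziness,dyspnea_worsening,edema,fatigue,other_flag logical
#'   red flags.
#' @param free_text optional free-text note.
#' @return a one-row tibble.
#' @export
symptom_report <- function(patient_id, date, dizziness = FALSE,
                           dyspnea_worsening = FALSE, edema = FALSE,
                           fatigue = FALSE, other_flag = FALSE,
                           free_text = NA_character_) {
  tibble::tibble(patient_id = as.character(patient_id),
                 date = as_date_scalar(date),
                 dizziness = isTRUE(dizziness),
                 dyspnea_worsening = isTRUE(dyspnea_worsening),
                 edema = isTRUE(edema), fatigue = isTRUE(fatigue),
                 other_flag = isTRUE(other_flag), free_text = free_text)
}

symptom_flags <- c("dizziness", "dyspnea_worsening", "edema", "fatigue",
                   "other_flag")

#' A kidney-function blood result
#'
#' @param patient_id patient identifier.
#' @param date analysis date.
#' @param egfr estimated glomerular filtration rate, mL/min/1.73m2;
#'   must be positive.
#' @param creatinine serum creatinine in mg/dL (optional).
#' @return a one-row tibble.
#' @export
blood_result <- function(patient_id, date, egfr, creatinine = NA_real_) {
  assert_that(is.numeric(egfr) && egfr > 0, "egfr must be positive")
  tibble::tibble(patient_id = as.character(patient_id),
                 date = as_date_scalar(date), egfr = as.numeric(egfr),
                 creatinine = as.numeric(creatinine))
}

#' Classify an uptitration proposal
#'
#' Pure decision function mapping the evidence gathered before a
#' proposal's due date to one of five outcomes. The rule cascade is
#' evaluated in order and the first matching branch wins:
#'
#' 1. patient already at the top ladder step, or the nurse has marked the
#'    optimal dose reached, for this drug class — `NO_UPTITRATION`;
#' 2. window completeness below `completeness_cutoff`, or the
#'    pre-proposal questionnaire missing — `NURSE_EVAL_INCOMPLETE`;
#' 3. any threshold crossing or sustained alert in the window —
#'    `NURSE_EVAL_ABERRANT_VITALS`;
#' 4. ACE-I proposals only: blood result missing or older than
#'    `blood_max_age_days` — `NURSE_EVAL_INCOMPLETE`; eGFR below
#'    `egfr_floor` or more than `egfr_drop_frac` below the enrollment
#'    baseline — `NURSE_EVAL_ABERRANT_BLOOD`;
#' 5. any symptom red flag set — `NURSE_EVAL_ABERRANT_VITALS`;
#' 6. otherwise — `UPTITRATE`.
#'
#' By construction no `UPTITRATE` outcome can coexist with an active
#' crossing: the design has a large safety margin and routes anything
#' suspicious to the nurse.
#'
#' @param event one row of the schedule from [build_schedule()].
#' @param quality a `data_quality` from [assess_window()].
#' @param plan the patient's [medication_plan()].
#' @param blood latest [blood_result()] for the patient, or `NULL`.
#' @param symptoms the pre-proposal [symptom_report()], or `NULL` if the
#'   questionnaire was not answered.
#' @param baseline_egfr enrollment eGFR used as reference for the
#'   relative-drop rule; `NA` disables that rule.
#' @param completeness_cutoff fraction of expected measurement days below
#'   which the window counts as incomplete.
#' @param egfr_floor absolute eGFR limit (mL/min/1.73m2).
#' @param egfr_drop_frac maximum tolerated relative eGFR drop from
#'   baseline.
#' @param blood_max_age_days a blood result older than this (relative to
#'   the due date) counts as missing.
#' @return a list of class `proposal`: the event fields plus `outcome`
#'   and an `evidence` snapshot (completeness, number of active
#'   crossings, eGFR used, symptom flags).
#' @export
classify_proposal <- function(event, quality, plan, blood = NULL,
                              symptoms = NULL, baseline_egfr = NA_real_,
                              completeness_cutoff = 0.8, egfr_floor = 30,
                              egfr_drop_frac = 0.25, blood_max_age_days = 14) {
  drug_class <- event$drug_class
  assert_that(drug_class %in% names(plan$drugs),
              paste0("configuration error: no ladder for drug class ", drug_class))
  blood_fresh <- !is.null(blood) && nrow(blood) > 0 &&
    as.integer(event$due_date - blood$date[nrow(blood)]) <= blood_max_age_days
  egfr <- if (blood_fresh) blood$egfr[nrow(blood)] else NA_real_
  flags <- if (!is.null(symptoms) && nrow(symptoms) > 0) {
    unlist(symptoms[nrow(symptoms), symptom_flags])
  } else NULL

  outcome <- if (at_top_step(plan, drug_class) ||
                 plan$drugs[[drug_class]]$at_optimal) {
    "NO_UPTITRATION"
  } else if (quality$completeness < completeness_cutoff || is.null(flags)) {
    "NURSE_EVAL_INCOMPLETE"
  } else if (quality$aberrant) {
    "NURSE_EVAL_ABERRANT_VITALS"
  } else if (drug_class == "ace_i" && !blood_fresh) {
    "NURSE_EVAL_INCOMPLETE"
  } else if (drug_class == "ace_i" &&
             (egfr < egfr_floor ||
              (!is.na(baseline_egfr) &&
               egfr < (1 - egfr_drop_frac) * baseline_egfr))) {
    "NURSE_EVAL_ABERRANT_BLOOD"
  } else if (any(flags)) {
    "NURSE_EVAL_ABERRANT_VITALS"
  } else {
    "UPTITRATE"
  }

  structure(
    list(patient_id = plan$patient_id, due_date = event$due_date,
         drug_class = drug_class, sequence_index = event$sequence_index,
         outcome = outcome,
         evidence = list(completeness = quality$completeness,
                         n_crossings = nrow(quality$crossings),
                         n_alerts = nrow(quality$alerts),
                         egfr = egfr, baseline_egfr = baseline_egfr,
                         questionnaire_answered = !is.null(flags),
                         symptom_flags = if (is.null(flags)) NA else any(flags))),
    class = "proposal")
}

#' @export
print.proposal <- function(x, ...) {
  cat(sprintf("<proposal> patient %s, %s #%d due %s: %s\n", x$patient_id,
              x$drug_class, x$sequence_index, format(x$due_date), x$outcome))
  invisible(x)
}

nurse_actions <- c("CONFIRM", "CONTACT_PATIENT_THEN_DECIDE",
                   "CHANGE_OTHER_MEDICATION", "LEAVE_UNCHANGED",
                   "OPTIMAL_REACHED")

#' Apply a nurse review to a proposal
#'
#' Every proposal is reviewed by a dedicated heart-failure nurse before
#' any change reaches the patient's phone. The review either confirms the
#' algorithm proposal, contacts the patient and then decides, changes
#' other medication, leaves the scheme unchanged, or declares the optimal
#' dose reached (which freezes further proposals for that drug class).
#'
#' A dose increase moves the ladder position up by exactly one step and
#' never past the top step: attempting to uptitrate at the guideline
#' maximum is a safety violation error, not a silent clamp. Any applied
#' change emits a patient notification that must be confirmed as a
#' pop-up on the next plan push.
#'
#' @param proposal a classified [classify_proposal()] result.
#' @param action one of `CONFIRM`, `CONTACT_PATIENT_THEN_DECIDE`,
#'   `CHANGE_OTHER_MEDICATION`, `LEAVE_UNCHANGED`, `OPTIMAL_REACHED`.
#' @param plan the patient's current [medication_plan()].
#' @param final_decision for `CONTACT_PATIENT_THEN_DECIDE` (mandatory):
#'   `"uptitrate"` or `"hold"`. For `CONFIRM` the decision follows the
#'   proposal outcome (`UPTITRATE` steps up, anything else holds).
#' @param note free-text nurse note for the audit record.
#' @return a list with `plan` (updated), `audit` (one-row tibble:
#'   patient, drug class, proposal outcome, action, decision, doses
#'   before/after, note) and `notification` (one-row tibble if the dose
#'   changed, else `NULL`).
#' @export
apply_review <- function(proposal, action, plan, final_decision = NULL,
                         note = NA_character_) {
  assert_that(inherits(proposal, "proposal"), "proposal must be classified first")
  assert_that(action %in% nurse_actions,
              paste0("unknown nurse action: ", action))
  assert_that(identical(proposal$patient_id, plan$patient_id),
              "proposal and plan belong to different patients")
  cls <- proposal$drug_class
  dose_before <- current_dose(plan, cls)

  decision <- switch(action,
    CONFIRM = if (proposal$outcome == "UPTITRATE") "uptitrate" else "hold",
    CONTACT_PATIENT_THEN_DECIDE = {
      assert_that(!is.null(final_decision) &&
                    final_decision %in% c("uptitrate", "hold"),
                  "CONTACT_PATIENT_THEN_DECIDE requires final_decision uptitrate/hold")
      final_decision
    },
    CHANGE_OTHER_MEDICATION = "hold",
    LEAVE_UNCHANGED = "hold",
    OPTIMAL_REACHED = "hold")

  if (decision == "uptitrate") {
    if (at_top_step(plan, cls)) {
      stop(sprintf("safety violation: %s already at guideline maximum (%g mg)",
                   plan$drugs[[cls]]$ladder$drug_name,
                   plan$drugs[[cls]]$ladder$max_daily), call. = FALSE)
    }
    plan$drugs[[cls]]$current_step_index <-
      plan$drugs[[cls]]$current_step_index + 1L
  }
  if (action == "OPTIMAL_REACHED") plan$drugs[[cls]]$at_optimal <- TRUE
  dose_after <- current_dose(plan, cls)

  audit <- tibble::tibble(
    patient_id = plan$patient_id, due_date = proposal$due_date,
    sequence_index = proposal$sequence_index, drug_class = cls,
    proposal_outcome = proposal$outcome, nurse_action = action,
    final_decision = decision, dose_before = dose_before,
    dose_after = dose_after, note = note)
  notification <- if (dose_after != dose_before) {
    tibble::tibble(type = "plan_change_popup", patient_id = plan$patient_id,
                   date = proposal$due_date, drug_class = cls,
                   dose = dose_after, requires_confirmation = TRUE)
  } else NULL
  list(plan = plan, audit = audit, notification = notification)
}

#' Daily medication-plan push
#'
#' The patient-specific medication scheme is uploaded to the smartphone
#' every morning. The message lists today's daily dose per drug (the
#' diuretic appears as monitored-only; the engine never changes it) and
#' flags whether anything changed since the previous day's message, in
#' which case the patient must confirm a pop-up.
#'
#' @param plan the patient's [medication_plan()].
#' @param date the push date.
#' @param previous the previous day's push message (or `NULL` on day 1).
#' @return a list of class `plan_push` with `patient_id`, `date`, `doses`
#'   (named list, mg), `changed` and `requires_confirmation`.
#' @export
daily_plan_push <- function(plan, date, previous = NULL) {
  doses <- list(beta_blocker = current_dose(plan, "beta_blocker"),
                ace_i = current_dose(plan, "ace_i"))
  if (plan$diuretic) doses$diuretic <- "monitored"
  changed <- !is.null(previous) && !identical(previous$doses, doses)
  structure(list(patient_id = plan$patient_id, date = as_date_scalar(date),
                 doses = doses, changed = changed,
                 requires_confirmation = changed),
            class = "plan_push")
}
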