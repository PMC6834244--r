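#' Vital-sign alert thresholds
#'
#' Threshold set against which each day's device measurements are checked.
#' A crossing that persists for `run_length` consecutive measured days
#' raises a sustained alert. Defaults are the monitoring thresholds used
#' for remote heart-failure follow-up: weight gain of 2 kg over the
#' enrollment baseline, heart rate outside (60, 100) bpm, systolic blood
#' pressure outside (90, 160) mm Hg and diastolic outside (60, 95) mm Hg,
#' each sustained for 3 consecutive days.
#'
#' Heart-rate and blood-pressure bounds are strict (`< low` or `> high`);
#' the weight bound is inclusive: a weight at or above baseline + 2 kg is
#' a crossing, because the stated alarm level is itself the gain of 2 kg.
#'
#' @param weight_gain kg above baseline weight that counts as a crossing.
#' @param hr_low,hr_high heart-rate bounds, beats per minute.
#' @param sbp_low,sbp_high systolic blood-pressure bounds, mm Hg.
#' @param dbp_low,dbp_high diastolic blood-pressure bounds, mm Hg.
#' @param run_length consecutive measured days required for a sustained
#'   alert.
#' @return an object of class `threshold_set`.
#' @export
threshold_set <- function(weight_gain = 2, hr_low = 60, hr_high = 100,
                          sbp_low = 90, sbp_high = 160,
                          dbp_low = 60, dbp_high = 95, run_length = 3) {
  assert_that(weight_gain > 0, "weight_gain must be positive")
  assert_that(hr_low < hr_high && sbp_low < sbp_high && dbp_low < dbp_high,
              "each low bound must be below its high bound")
  assert_that(run_length >= 1, "run_length must be >= 1")
  structure(
    list(weight_gain = weight_gain, hr_low = hr_low, hr_high = hr_high,
         sbp_low = sbp_low, sbp_high = sbp_high, dbp_low = dbp_low,
         dbp_high = dbp_high, run_length = as.integer(run_length)),
    class = "threshold_set"
  )
}

#' A single day's vital-sign sample
#'
#' One accepted measurement set for one patient on one calendar date.
#' Any vital may be missing (`NA`); present values must be strictly
#' positive.
#'
#' @param patient_id patient identifier.
#' @param date measurement date (`Date` or coercible).
#' @param weight body weight in kg, or `NA`.
#' @param systolic,diastolic blood pressure in mm Hg, or `NA`.
#' @param heart_rate heart rate in bpm, or `NA`.
#' @param source `"device_auto"` for automatic device transmission or
#'   `"callcenter_phone"` for values collected over the phone after a
#'   technical failure.
#' @param recorded_at timestamp of the recording; defaults to noon of
#'   `date`.
#' @return a one-row [tibble::tibble()] with class `vital_sample`.
#' @export
vital_sample <- function(patient_id, date, weight = NA_real_,
                         systolic = NA_real_, diastolic = NA_real_,
                         heart_rate = NA_real_,
                         source = c("device_auto", "callcenter_phone"),
                         recorded_at = NULL) {
  source <- match.arg(source)
  date <- as_date_scalar(date)
  vals <- c(weight = weight, systolic = systolic, diastolic = diastolic,
            heart_rate = heart_rate)
  if (any(!is.na(vals) & vals <= 0)) {
    stop("rejected sample: vital values must be strictly positive",
         call. = FALSE)
  }
  if (all(is.na(vals))) {
    stop("rejected sample: at least one vital must be present", call. = FALSE)
  }
  recorded_at <- recorded_at %||%
    as.POSIXct(paste(format(date), "12:00:00"), tz = "UTC")
  assert_that(as.Date(recorded_at, tz = "UTC") == date,
              "recorded_at must fall on the sample date")
  out <- tibble::tibble(
    patient_id = as.character(patient_id), date = date,
    weight = as.numeric(weight), systolic = as.numeric(systolic),
    diastolic = as.numeric(diastolic), heart_rate = as.numeric(heart_rate),
    source = source, recorded_at = recorded_at
  )
  class(out) <- c("vital_sample", class(out))
  out
}

vital_parameters <- c("weight", "heart_rate", "systolic", "diastolic")

empty_crossings <- function() {
  tibble::tibble(patient_id = character(), date = as.Date(character()),
                 parameter = character(), direction = character(),
                 value = numeric())
}

#' Evaluate one vital sample against thresholds
#'
#' Pure, stateless check of a single day's measurements. Emits one
#' crossing row per violated bound; vitals absent from the sample produce
#' nothing. Heart-rate and blood-pressure comparisons are strict
#' (a heart rate of exactly 60 bpm is not a crossing); the weight rule is
#' inclusive (weight at exactly baseline + 2 kg is a crossing).
#'
#' @param sample a [vital_sample()] (or one-row data frame with the same
#'   columns).
#' @param baseline_weight the enrollment-day weight in kg; never updated
#'   automatically during follow-up.
#' @param thresholds a [threshold_set()].
#' @return a tibble of crossings with columns `patient_id`, `date`,
#'   `parameter` (`weight`, `heart_rate`, `systolic`, `diastolic`),
#'   `direction` (`low`/`high`; weight is always `high`) and `value`.
#' @export
#' @examples
#' s <- vital_sample("p1", "2026-01-05", heart_rate = 55, systolic = 120)
#' evaluate_sample(s, baseline_weight = 80)
evaluate_sample <- function(sample, baseline_weight, thresholds = threshold_set()) {
  assert_that(is.numeric(baseline_weight) && length(baseline_weight) == 1 &&
                baseline_weight > 0, "baseline_weight must be a positive scalar")
  assert_that(nrow(sample) == 1L, "evaluate_sample takes a single sample")
  vals <- c(weight = sample$weight, heart_rate = sample$heart_rate,
            systolic = sample$systolic, diastolic = sample$diastolic)
  if (any(!is.na(vals) & vals <= 0)) {
    stop("rejected sample: vital values must be strictly positive",
         call. = FALSE)
  }
  th <- thresholds
  rows <- list()
  add <- function(parameter, direction, value) {
    rows[[length(rows) + 1L]] <<- fast_row(
      patient_id = sample$patient_id, date = sample$date,
      parameter = parameter, direction = direction, value = value)
  }
  if (!is.na(sample$weight) &&
      sample$weight >= baseline_weight + th$weight_gain) {
    add("weight", "high", sample$weight)
  }
  if (!is.na(sample$heart_rate)) {
    if (sample$heart_rate < th$hr_low) add("heart_rate", "low", sample$heart_rate)
    if (sample$heart_rate > th$hr_high) add("heart_rate", "high", sample$heart_rate)
  }
  if (!is.na(sample$systolic)) {
    if (sample$systolic < th$sbp_low) add("systolic", "low", sample$systolic)
    if (sample$systolic > th$sbp_high) add("systolic", "high", sample$systolic)
  }
  if (!is.na(sample$diastolic)) {
    if (sample$diastolic < th$dbp_low) add("diastolic", "low", sample$diastolic)
    if (sample$diastolic > th$dbp_high) add("diastolic", "high", sample$diastolic)
  }
  if (length(rows) == 0) empty_crossings() else do.call(rbind, rows)
}

#' Evaluate a stream of samples for one or more patients
#'
#' Convenience wrapper applying [evaluate_sample()] row by row.
#'
#' @param samples a tibble of samples (columns as in [vital_sample()]).
#' @param baseline_weights named numeric vector of enrollment weights,
#'   names are patient ids.
#' @param thresholds a [threshold_set()].
#' @return a tibble of crossings (see [evaluate_sample()]).
#' @export
evaluate_samples <- function(samples, baseline_weights,
                             thresholds = threshold_set()) {
  if (nrow(samples) == 0) return(empty_crossings())
  out <- lapply(seq_len(nrow(samples)), function(i) {
    row <- samples[i, ]
    bw <- baseline_weights[[row$patient_id]]
    assert_that(!is.null(bw), paste0("no baseline weight for patient ", row$patient_id))
    evaluate_sample(row, bw, thresholds)
  })
  do.call(rbind, c(out, list(empty_crossings())))
}

#' Detect sustained threshold crossings
#'
#' Scans one patient's date-ordered crossing history for runs where the
#' same parameter is crossed on `run_length` consecutive calendar days,
#' each of those days having a valid measurement of that parameter. A day
#' with a valid measurement but no crossing, or a day with no measurement
#' at all, breaks the run. Exactly one alert is emitted per maximal run:
#' the alert covers the first `run_length` days of the run and does not
#' re-fire while the crossing continues; the run must end before that
#' parameter can alert again.
#'
#' @param crossings tibble of crossings for one patient, as produced by
#'   [evaluate_sample()], sorted by date, at most one row per
#'   (date, parameter).
#' @param measured tibble with columns `date`, `parameter` listing the
#'   days on which each parameter had a valid measurement.
#' @param thresholds a [threshold_set()] (supplies `run_length`).
#' @return a tibble of sustained alerts with columns `patient_id`,
#'   `parameter`, `run_start`, `run_end`.
#' @export
detect_sustained <- function(crossings, measured, thresholds = threshold_set()) {
  k <- thresholds$run_length
  empty <- tibble::tibble(patient_id = character(), parameter = character(),
                          run_start = as.Date(character()),
                          run_end = as.Date(character()))
  if (nrow(crossings) == 0) return(empty)
  assert_that(length(unique(crossings$patient_id)) == 1L,
              "detect_sustained takes one patient's history")
  assert_that(!is.unsorted(crossings$date),
              "contract violation: crossings must be sorted by date")
  assert_that(!anyDuplicated(crossings[, c("date", "parameter")]),
              "contract violation: one crossing per (date, parameter)")
  pid <- crossings$patient_id[[1]]
  alerts <- list()
  for (param in unique(crossings$parameter)) {
    cross_days <- sort(crossings$date[crossings$parameter == param])
    meas_days <- sort(unique(measured$date[measured$parameter == param]))
    # a run day must be both measured and crossed; by construction a
    # crossing day is measured, so runs are consecutive crossing days
    assert_that(all(cross_days %in% meas_days),
                "contract violation: crossing on a day without a measurement")
    run_start <- cross_days[1]
    prev <- cross_days[1]
    close_run <- function(start, end) {
      if (as.integer(end - start) + 1L >= k) {
        alerts[[length(alerts) + 1L]] <<- tibble::tibble(
          patient_id = pid, parameter = param,
          run_start = start, run_end = start + k - 1L)
      }
    }
    if (length(cross_days) > 1) {
      for (d in seq(2, length(cross_days))) {
        if (as.integer(cross_days[d] - prev) == 1L) {
          prev <- cross_days[d]
        } else {
          close_run(run_start, prev)
          run_start <- cross_days[d]
          prev <- cross_days[d]
        }
      }
    }
    close_run(run_start, prev)
  }
  if (length(alerts) == 0) return(empty)
  out <- do.call(rbind, alerts)
  out[order(out$run_end, out$parameter), ]
}

#' Dispatch events for sustained alerts
#'
#' For each sustained alert, pushes the heart-failure symptom
#' questionnaire to the patient (dated the run end) and opens a review
#' task for the clinical call center. Review tasks arising on a weekend
#' become visible on the next working day. When several parameters alert
#' with the same run end for the same patient, the questionnaire push is
#' collapsed to one; each alert still gets its own review task.
#'
#' @param alerts tibble of sustained alerts from [detect_sustained()].
#'   An alert must not be dispatched twice; duplicated rows raise an
#'   error.
#' @param calendar a [work_calendar()].
#' @return a tibble of dispatched events with columns `type`
#'   (`questionnaire_push` / `clinical_review`), `patient_id`,
#'   `parameter` (`NA` for the collapsed questionnaire push), `date`
#'   (the run end) and `visible_on` (deferred for weekends).
#' @export
dispatch_alerts <- function(alerts, calendar = work_calendar()) {
  empty <- tibble::tibble(type = character(), patient_id = character(),
                          parameter = character(),
                          date = as.Date(character()),
                          visible_on = as.Date(character()))
  if (nrow(alerts) == 0) return(empty)
  if (anyDuplicated(alerts[, c("patient_id", "parameter", "run_end")])) {
    stop("idempotency error: alert already dispatched", call. = FALSE)
  }
  q <- unique(alerts[, c("patient_id", "run_end")])
  pushes <- tibble::tibble(
    type = "questionnaire_push", patient_id = q$patient_id,
    parameter = NA_character_, date = q$run_end, visible_on = q$run_end)
  reviews <- tibble::tibble(
    type = "clinical_review", patient_id = alerts$patient_id,
    parameter = alerts$parameter, date = alerts$run_end,
    visible_on = as.Date(vapply(alerts$run_end, function(d)
      as.character(next_working_day(calendar, d)), character(1))))
  rbind(pushes, reviews)
}
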