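#' Simulation configuration
#'
#' Parameters for the synthetic cohort generator. Baseline vital
#' distributions default to the intervention-arm characteristics of a
#' small heart-failure uptitration cohort: heart rate 73 (13) bpm,
#' systolic pressure 112 (14) mm Hg, diastolic 75 (12) mm Hg, eGFR
#' 50 (28) mL/min/1.73m2; weight is drawn around 81 kg (BMI 28 at
#' average stature). Draws are truncated to physiologic ranges.
#'
#' Behaviour defaults mirror observed engagement: an in-window app
#' confirmation probability of 0.77, a small in-app decline probability,
#' a technical-failure probability of 0.13 for device transmissions, and
#' a phone-confirmation probability such that most escalated actions are
#' recovered by the call center.
#'
#' @param n_patients number of patients in the cohort.
#' @param n_days follow-up length in days (182 = 6 months).
#' @param seed integer RNG seed; a fixed seed makes the whole event
#'   stream reproducible.
#' @param enrollment_date cohort enrollment `Date` (day 0).
#' @param calendar a [work_calendar()].
#' @param baseline_mean,baseline_sd named numeric vectors over
#'   `weight`, `hr`, `sbp`, `dbp`, `egfr`.
#' @param behavior named list of probabilities: `p_confirm_app`,
#'   `p_decline` (in-window decline), `p_confirm_call` (confirmation
#'   probability when phoned after escalation), `p_tech_failure`
#'   (device transmission failure), `p_symptom` (daily probability of a
#'   red-flag symptom report around a proposal).
#' @param dose_response per drug class, per-step additive effect on
#'   vitals (bpm / mm Hg per ladder step above step 1): a list with
#'   `beta_blocker` and `ace_i`, each `c(hr=, sbp=, dbp=)`.
#' @param noise_sd per-parameter daily Gaussian noise SD:
#'   `c(weight=, hr=, sbp=, dbp=)`.
#' @param meds_per_day scheduled medication intakes per drug per day.
#' @param med_times,vitals_time clock hours of the scheduled actions.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 14, n_days = 182, seed = 1L,
                       enrollment_date = as.Date("2026-01-05"),
                       calendar = work_calendar(),
                       baseline_mean = c(weight = 81, hr = 73, sbp = 112,
                                         dbp = 75, egfr = 50),
                       baseline_sd = c(weight = 15, hr = 13, sbp = 14,
                                       dbp = 12, egfr = 28),
                       behavior = list(p_confirm_app = 0.77, p_decline = 0.03,
                                       p_confirm_call = 0.75,
                                       p_tech_failure = 0.13,
                                       p_symptom = 0.05),
                       dose_response = list(
                         beta_blocker = c(hr = -2, sbp = -2, dbp = -1),
                         ace_i = c(hr = 0, sbp = -3, dbp = -2)),
                       noise_sd = c(weight = 0.5, hr = 3, sbp = 5, dbp = 4),
                       meds_per_day = 1, med_times = c(8, 12, 18),
                       vitals_time = 8) {
  assert_that(n_days >= 1 && n_patients >= 1, "need n_days >= 1, n_patients >= 1")
  assert_that(all(c("weight", "hr", "sbp", "dbp", "egfr") %in%
                    names(baseline_mean)) && all(baseline_sd >= 0),
              "invalid baseline distribution parameters")
  probs <- unlist(behavior)
  assert_that(all(probs >= 0 & probs <= 1),
              "configuration error: behaviour probabilities must lie in [0,1]")
  assert_that(behavior$p_confirm_app + behavior$p_decline <= 1,
              "configuration error: p_confirm_app + p_decline must be <= 1")
  structure(
    list(n_patients = as.integer(n_patients), n_days = as.integer(n_days),
         seed = as.integer(seed),
         enrollment_date = as_date_scalar(enrollment_date),
         calendar = calendar, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, behavior = behavior,
         dose_response = dose_response, noise_sd = noise_sd,
         meds_per_day = meds_per_day, med_times = med_times,
         vitals_time = vitals_time),
    class = "sim_config")
}

physiologic_range <- list(weight = c(35, 250), hr = c(30, 220),
                          sbp = c(60, 260), dbp = c(30, 160),
                          egfr = c(5, 150))

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Draw one synthetic patient profile
#'
#' Baseline vitals are drawn from the configured normal distributions,
#' truncated to physiologic ranges; behaviour probabilities are taken
#' from the configuration. With an SD of zero every patient's baseline
#' equals the mean exactly. The RNG substream is derived from
#' `(seed, patient index)` so profiles are reproducible regardless of
#' simulation order.
#'
#' @param config a [sim_config()].
#' @param index 1-based patient index in the cohort.
#' @return a list of class `patient_profile` with `patient_id`,
#'   `baseline` (named numeric), `behavior`, `dose_response`, `noise_sd`.
#' @export
sample_profile <- function(config, index) {
  set.seed(substream_seed(config$seed, index))
  nm <- c("weight", "hr", "sbp", "dbp", "egfr")
  baseline <- vapply(nm, function(p) {
    r <- physiologic_range[[p]]
    rtrunc_norm(1, config$baseline_mean[[p]], config$baseline_sd[[p]],
                r[1], r[2])
  }, numeric(1))
  structure(
    list(patient_id = sprintf("P%03d", index), index = index,
         baseline = baseline, behavior = config$behavior,
         dose_response = config$dose_response, noise_sd = config$noise_sd),
    class = "patient_profile")
}

dose_effect <- function(profile, plan) {
  eff <- c(hr = 0, sbp = 0, dbp = 0)
  for (cls in names(plan$drugs)) {
    steps_above <- plan$drugs[[cls]]$current_step_index - 1L
    eff <- eff + steps_above * profile$dose_response[[cls]][c("hr", "sbp", "dbp")]
  }
  eff
}

#' Simulate one follow-up day for one patient
#'
#' Vitals are the baseline plus the cumulative (linear-in-step,
#' immediate) dose response at the current ladder positions plus
#' Gaussian noise. With probability `p_tech_failure` the device
#' transmission fails and the sample is later recovered over the phone
#' (`source = "callcenter_phone"`). Responses to each scheduled action
#' are drawn from the behaviour probabilities.
#'
#' @param profile a [sample_profile()] result.
#' @param plan the patient's current [medication_plan()].
#' @param date simulation date.
#' @param tech_failed logical: did the device transmission fail today?
#'   (drawn by the caller so the RNG stream is explicit).
#' @return a one-row tibble of the day's vital sample.
#' @export
simulate_day_vitals <- function(profile, plan, date, tech_failed = FALSE) {
  eff <- dose_effect(profile, plan)
  b <- profile$baseline
  ns <- profile$noise_sd
  vital_sample(
    profile$patient_id, date,
    weight = max(35, b[["weight"]] + stats::rnorm(1, 0, ns[["weight"]])),
    heart_rate = max(30, b[["hr"]] + eff[["hr"]] + stats::rnorm(1, 0, ns[["hr"]])),
    systolic = max(60, b[["sbp"]] + eff[["sbp"]] + stats::rnorm(1, 0, ns[["sbp"]])),
    diastolic = max(30, b[["dbp"]] + eff[["dbp"]] + stats::rnorm(1, 0, ns[["dbp"]])),
    source = if (tech_failed) "callcenter_phone" else "device_auto")
}

# draw the patient's response stream for one scheduled action
draw_responses <- function(profile, action, tech_failed = FALSE) {
  bh <- profile$behavior
  u <- stats::runif(1)
  if (!tech_failed && u < bh$p_confirm_app) {
    # complete somewhere in the window (uniform offset)
    t <- action$window_open +
      stats::runif(1, 0, as.numeric(action$window_close - action$window_open,
                                    units = "secs"))
    fast_row(time = t, channel = "app", response = "confirm")
  } else if (!tech_failed && u < bh$p_confirm_app + bh$p_decline) {
    t <- action$window_open +
      stats::runif(1, 0, as.numeric(action$window_close - action$window_open,
                                    units = "secs"))
    fast_row(time = t, channel = "app", response = "decline")
  } else {
    # escalated: what the patient reports when the call center phones;
    # the call instant itself is fixed by the calendar in lifecycle()
    said <- if (stats::runif(1) < bh$p_confirm_call) "confirm"
    else if (action$kind == "medication_intake") "decline" else "none"
    out <- tibble::tibble(time = as.POSIXct(character(), tz = "UTC"),
                          channel = character(), response = character())
    attr(out, "call_said") <- said
    out
  }
}

#' Simulate a whole cohort
#'
#' Generates the full day-by-day event stream for a synthetic cohort and
#' pipes every scheduled action through the engagement lifecycle, the
#' telemetry monitor over all vital samples, and the titration engine at
#' each biweekly proposal date (with an automatic nurse policy that
#' confirms proposals, phones the patient on aberrant-vitals proposals
#' and then holds, and declares optimal when the top step is reached).
#' Returns the stream plus the ground-truth parameters for recovery
#' tests.
#'
#' @param config a [sim_config()].
#' @param nurse_policy a function `(proposal, plan) -> list(action=,
#'   final_decision=)`; the default implements the policy above.
#' @return a list of class `cohort_sim` with elements `samples`,
#'   `ledger`, `events`, `calls`, `crossings`, `alerts`, `proposals`
#'   (tibble), `audit`, `plans` (final plans), `plan_history` (per
#'   patient per proposal dose trajectory), `profiles`, `truth`
#'   (the configuration), `schedule`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            nurse_policy = default_nurse_policy) {
  schedule <- build_schedule(config$enrollment_date)
  samples_l <- list(); ledger_l <- list(); events_l <- list()
  calls_l <- list(); props_l <- list(); audit_l <- list(); hist_l <- list()
  crossings_l <- list(); alerts_l <- list()
  profiles <- vector("list", config$n_patients)
  plans <- vector("list", config$n_patients)

  for (i in seq_len(config$n_patients)) {
    profile <- sample_profile(config, i)
    profiles[[i]] <- profile
    set.seed(substream_seed(config$seed, 100000L + i))
    plan <- medication_plan(profile$patient_id)
    baseline_weight <- profile$baseline[["weight"]]
    baseline_egfr <- profile$baseline[["egfr"]]
    psamples <- list(); pledger <- list(); pevents <- list(); pcalls <- list()
    next_prop <- 1L

    for (d in seq_len(config$n_days) - 1L) {
      date <- config$enrollment_date + d
      tech_failed <- stats::runif(1) < profile$behavior$p_tech_failure

      # proposals due today are classified before the day's events
      while (next_prop <= nrow(schedule) &&
             schedule$due_date[next_prop] == date) {
        ev <- schedule[next_prop, ]
        win_samples <- if (length(psamples))
          do.call(rbind, psamples) else vital_sample(profile$patient_id,
                                                     date, weight = baseline_weight)[0, ]
        quality <- assess_window(win_samples, ev$due_date, baseline_weight)
        blood <- if (ev$drug_class == "ace_i") {
          set_egfr <- baseline_egfr * stats::rnorm(1, 1, 0.05)
          blood_result(profile$patient_id, ev$blood_request_date,
                       egfr = max(5, set_egfr))
        } else NULL
        symptoms <- if (stats::runif(1) < 0.95) {
          symptom_report(profile$patient_id, date,
                         dizziness = stats::runif(1) < profile$behavior$p_symptom)
        } else NULL
        prop <- classify_proposal(ev, quality, plan, blood = blood,
                                  symptoms = symptoms,
                                  baseline_egfr = baseline_egfr)
        pol <- nurse_policy(prop, plan)
        rev <- apply_review(prop, pol$action, plan,
                            final_decision = pol$final_decision)
        plan <- rev$plan
        props_l[[length(props_l) + 1L]] <- tibble::tibble(
          patient_id = prop$patient_id, due_date = prop$due_date,
          sequence_index = prop$sequence_index, drug_class = prop$drug_class,
          outcome = prop$outcome,
          n_crossings = prop$evidence$n_crossings,
          n_alerts = prop$evidence$n_alerts,
          completeness = prop$evidence$completeness)
        audit_l[[length(audit_l) + 1L]] <- rev$audit
        hist_l[[length(hist_l) + 1L]] <- tibble::tibble(
          patient_id = plan$patient_id, date = date,
          beta_blocker_step = plan$drugs$beta_blocker$current_step_index,
          ace_i_step = plan$drugs$ace_i$current_step_index)
        next_prop <- next_prop + 1L
      }

      # daily vitals measurement action
      s <- simulate_day_vitals(profile, plan, date, tech_failed)
      vit_action <- scheduled_action(
        profile$patient_id, "vital_measurement",
        as.POSIXct(paste(format(date), sprintf("%02d:00:00", config$vitals_time)),
                   tz = "UTC"))
      vit_resp <- draw_responses(profile, vit_action, tech_failed)
      res <- lifecycle(vit_action, vit_resp, config$calendar,
                       unanswered = attr(vit_resp, "call_said"))
      pledger[[length(pledger) + 1L]] <- res$ledger
      pevents[[length(pevents) + 1L]] <- res$events
      if (!is.null(res$call)) pcalls[[length(pcalls) + 1L]] <- res$call
      if (res$ledger$outcome != "no_recording") psamples[[length(psamples) + 1L]] <- s

      # medication intake actions (one per drug per day by default)
      for (drug in c("beta_blocker", "ace_i", "diuretic")) {
        slot <- match(drug, c("beta_blocker", "ace_i", "diuretic"))
        hour <- config$med_times[[(slot - 1L) %% length(config$med_times) + 1L]]
        act <- scheduled_action(
          profile$patient_id, "medication_intake",
          as.POSIXct(paste(format(date), sprintf("%02d:00:00", hour)), tz = "UTC"),
          drug = drug)
        resp <- draw_responses(profile, act, tech_failed = FALSE)
        res <- lifecycle(act, resp, config$calendar,
                         unanswered = attr(resp, "call_said"))
        pledger[[length(pledger) + 1L]] <- res$ledger
        pevents[[length(pevents) + 1L]] <- res$events
        if (!is.null(res$call)) pcalls[[length(pcalls) + 1L]] <- res$call
      }
    }

    psample_tbl <- if (length(psamples)) do.call(rbind, psamples) else NULL
    if (!is.null(psample_tbl)) {
      cr <- evaluate_samples(psample_tbl,
                             stats::setNames(baseline_weight, profile$patient_id))
      al <- detect_sustained(cr, window_measured(psample_tbl))
      crossings_l[[i]] <- cr; alerts_l[[i]] <- al
      samples_l[[i]] <- psample_tbl
    }
    ledger_l[[i]] <- do.call(rbind, pledger)
    events_l[[i]] <- do.call(rbind, pevents)
    if (length(pcalls)) calls_l[[i]] <- do.call(rbind, pcalls)
    plans[[i]] <- plan
  }

  structure(
    list(samples = do.call(rbind, samples_l),
         ledger = do.call(rbind, ledger_l),
         events = do.call(rbind, events_l),
         calls = if (length(calls_l)) do.call(rbind, calls_l) else
           tibble::tibble(patient_id = character(), placed_at =
                            as.POSIXct(character(), tz = "UTC"),
                          reason = character(), kind = character(),
                          drug = character()),
         crossings = do.call(rbind, crossings_l),
         alerts = do.call(rbind, alerts_l),
         proposals = if (length(props_l)) do.call(rbind, props_l) else
           tibble::tibble(patient_id = character(),
                          due_date = as.Date(character()),
                          sequence_index = integer(), drug_class = character(),
                          outcome = character(), n_crossings = integer(),
                          n_alerts = integer(), completeness = numeric()),
         audit = if (length(audit_l)) do.call(rbind, audit_l) else NULL,
         plan_history = if (length(hist_l)) do.call(rbind, hist_l) else NULL,
         plans = plans, profiles = profiles, truth = config,
         schedule = schedule),
    class = "cohort_sim")
}

#' Default automatic nurse policy for simulations
#'
#' Confirms `UPTITRATE` and `NO_UPTITRATION` proposals; on
#' `NURSE_EVAL_ABERRANT_VITALS` or `NURSE_EVAL_ABERRANT_BLOOD` phones the
#' patient and holds; on `NURSE_EVAL_INCOMPLETE` leaves the scheme
#' unchanged; declares `OPTIMAL_REACHED` when the proposal finds the
#' patient at the top ladder step.
#'
#' @param proposal a classified proposal.
#' @param plan the patient's plan.
#' @return list with `action` and `final_decision`.
#' @export
default_nurse_policy <- function(proposal, plan) {
  if (proposal$outcome == "NO_UPTITRATION" &&
      at_top_step(plan, proposal$drug_class)) {
    return(list(action = "OPTIMAL_REACHED", final_decision = NULL))
  }
  switch(proposal$outcome,
    UPTITRATE = list(action = "CONFIRM", final_decision = NULL),
    NO_UPTITRATION = list(action = "CONFIRM", final_decision = NULL),
    NURSE_EVAL_INCOMPLETE = list(action = "LEAVE_UNCHANGED",
                                 final_decision = NULL),
    list(action = "CONTACT_PATIENT_THEN_DECIDE", final_decision = "hold"))
}
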