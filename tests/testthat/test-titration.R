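test_that("default 91-day phase yields 6 alternating proposals", {
  s <- build_schedule(d0)
  expect_equal(nrow(s), 6L)
  expect_equal(as.integer(s$due_date - d0), c(14, 28, 42, 56, 70, 84))
  expect_equal(s$drug_class, rep(c("beta_blocker", "ace_i"), 3))
  # blood requests one week before each ACE-I proposal
  expect_equal(as.integer(s$blood_request_date[s$drug_class == "ace_i"] - d0),
               c(21, 49, 77))
  expect_true(all(is.na(s$blood_request_date[s$drug_class == "beta_blocker"])))
  # pre-proposal questionnaire accompanies every event
  expect_equal(s$questionnaire_due_date, s$due_date)
  expect_equal(format(s$proposal_time[1], "%H:%M", tz = "UTC"), "08:00")
})

test_that("schedule arithmetic scales with the phase length", {
  expect_equal(nrow(build_schedule(d0, active_phase_days = 14)), 1L)
  expect_equal(build_schedule(d0, active_phase_days = 14)$drug_class,
               "beta_blocker")
  for (days in c(28, 56, 91, 120, 182)) {
    expect_equal(nrow(build_schedule(d0, active_phase_days = days)),
                 floor(days / 14))
  }
  expect_error(build_schedule(d0, active_phase_days = 10), "at least one")
})

test_that("window assessment measures completeness and aberrance", {
  due <- d0 + 14
  win <- clean_window(due)
  q <- assess_window(win, due, baseline_weight = 80)
  expect_equal(q$completeness, 1.0)
  expect_false(q$aberrant)

  q10 <- assess_window(win[1:10, ], due, baseline_weight = 80)
  expect_equal(q10$completeness, 10 / 14, tolerance = 1e-12)

  win2 <- win
  win2$heart_rate[5] <- 55
  q2 <- assess_window(win2, due, baseline_weight = 80)
  expect_true(q2$aberrant)
  expect_equal(q2$crossings$parameter, "heart_rate")
})

test_that("ladders enforce guideline maxima", {
  lad <- default_ladders()
  expect_equal(lad$bisoprolol$max_daily, 10)
  expect_equal(lad$nebivolol$max_daily, 5)
  expect_equal(lad$enalapril$max_daily, 10)
  expect_equal(lad$lisinopril$max_daily, 20)
  expect_equal(lad$candesartan$max_daily, 16)
  expect_equal(lad$losartan$max_daily, 100)
  expect_error(dose_ladder("bisoprolol", "beta_blocker", c(1.25, 2.5, 5, 12)),
               "guideline maximum")
  expect_error(dose_ladder("x", "ace_i", c(5, 5, 10)), "strictly increasing")
})

make_clean_evidence <- function(due = d0 + 14) {
  list(quality = assess_window(clean_window(due), due, baseline_weight = 80),
       blood = blood_result("p1", due - 7, egfr = 70),
       symptoms = symptom_report("p1", due))
}

test_that("the rule cascade classifies in the documented order", {
  sched <- build_schedule(d0)
  plan <- medication_plan("p1", bb_step = 2, ace_step = 2)
  ev_bb <- sched[1, ]; ev_ace <- sched[2, ]
  e <- make_clean_evidence()

  # clean, complete, mid-ladder: conclusive uptitration
  p <- classify_proposal(ev_bb, e$quality, plan, blood = e$blood,
                         symptoms = e$symptoms, baseline_egfr = 70)
  expect_equal(p$outcome, "UPTITRATE")

  # top step wins over everything else
  plan_top <- medication_plan("p1", bb_step = 6)
  expect_equal(classify_proposal(ev_bb, e$quality, plan_top)$outcome,
               "NO_UPTITRATION")

  # incomplete window
  thin <- assess_window(clean_window(ev_bb$due_date, n = 10), ev_bb$due_date, 80)
  expect_equal(classify_proposal(ev_bb, thin, plan, blood = e$blood,
                                 symptoms = e$symptoms)$outcome,
               "NURSE_EVAL_INCOMPLETE")

  # missing questionnaire counts as incomplete
  expect_equal(classify_proposal(ev_bb, e$quality, plan, blood = e$blood,
                                 symptoms = NULL)$outcome,
               "NURSE_EVAL_INCOMPLETE")

  # aberrant vitals dominate blood and symptoms
  win <- clean_window(ev_bb$due_date); win$heart_rate[3] <- 55
  q_ab <- assess_window(win, ev_bb$due_date, 80)
  expect_equal(classify_proposal(ev_bb, q_ab, plan, blood = e$blood,
                                 symptoms = e$symptoms)$outcome,
               "NURSE_EVAL_ABERRANT_VITALS")

  # ACE-I with low eGFR
  e2 <- make_clean_evidence(ev_ace$due_date)
  low <- blood_result("p1", ev_ace$due_date - 7, egfr = 25)
  expect_equal(classify_proposal(ev_ace, e2$quality, plan, blood = low,
                                 symptoms = e2$symptoms)$outcome,
               "NURSE_EVAL_ABERRANT_BLOOD")

  # ACE-I with a >25% drop from baseline
  drop <- blood_result("p1", ev_ace$due_date - 7, egfr = 40)
  expect_equal(classify_proposal(ev_ace, e2$quality, plan, blood = drop,
                                 symptoms = e2$symptoms,
                                 baseline_egfr = 60)$outcome,
               "NURSE_EVAL_ABERRANT_BLOOD")

  # ACE-I with stale or missing blood is incomplete, not aberrant
  stale <- blood_result("p1", ev_ace$due_date - 20, egfr = 70)
  expect_equal(classify_proposal(ev_ace, e2$quality, plan, blood = stale,
                                 symptoms = e2$symptoms)$outcome,
               "NURSE_EVAL_INCOMPLETE")
  expect_equal(classify_proposal(ev_ace, e2$quality, plan, blood = NULL,
                                 symptoms = e2$symptoms)$outcome,
               "NURSE_EVAL_INCOMPLETE")

  # symptom red flag routes to the nurse
  sym <- symptom_report("p1", ev_bb$due_date, dizziness = TRUE)
  expect_equal(classify_proposal(ev_bb, e$quality, plan, blood = e$blood,
                                 symptoms = sym)$outcome,
               "NURSE_EVAL_ABERRANT_VITALS")
})

test_that("classification is a pure function of the evidence", {
  sched <- build_schedule(d0)
  plan <- medication_plan("p1", bb_step = 2)
  e <- make_clean_evidence()
  p1 <- classify_proposal(sched[1, ], e$quality, plan, blood = e$blood,
                          symptoms = e$symptoms, baseline_egfr = 70)
  p2 <- classify_proposal(sched[1, ], e$quality, plan, blood = e$blood,
                          symptoms = e$symptoms, baseline_egfr = 70)
  expect_identical(p1$outcome, p2$outcome)
  expect_identical(p1$evidence, p2$evidence)
})

test_that("an uptitration proposal never coexists with an active crossing", {
  # across random evidence, outcome UPTITRATE implies zero crossings
  set.seed(33)
  sched <- build_schedule(d0)
  for (i in 1:40) {
    plan <- medication_plan("p1", bb_step = sample(1:6, 1),
                            ace_step = sample(1:3, 1))
    ev <- sched[sample(1:6, 1), ]
    win <- clean_window(ev$due_date, n = sample(c(10, 14), 1))
    if (stats::runif(1) < 0.5) win$heart_rate[2] <- sample(c(50, 110), 1)
    q <- assess_window(win, ev$due_date, 80)
    p <- classify_proposal(ev, q, plan,
                           blood = blood_result("p1", ev$due_date - 3,
                                                egfr = stats::runif(1, 20, 90)),
                           symptoms = symptom_report("p1", ev$due_date),
                           baseline_egfr = 60)
    if (p$outcome == "UPTITRATE") {
      expect_equal(p$evidence$n_crossings, 0L)
      expect_equal(p$evidence$n_alerts, 0L)
    }
  }
})

test_that("a confirmed uptitration moves exactly one ladder step", {
  plan <- medication_plan("p1", bb_step = 2)  # bisoprolol 2.5 mg
  sched <- build_schedule(d0)
  e <- make_clean_evidence()
  p <- classify_proposal(sched[1, ], e$quality, plan, blood = e$blood,
                         symptoms = e$symptoms)
  expect_equal(p$outcome, "UPTITRATE")
  r <- apply_review(p, "CONFIRM", plan)
  expect_equal(current_dose(r$plan, "beta_blocker"), 3.75)
  expect_equal(r$audit$dose_before, 2.5)
  expect_equal(r$audit$dose_after, 3.75)
  expect_equal(r$notification$type, "plan_change_popup")
  expect_true(r$notification$requires_confirmation)
})

test_that("contact-then-hold leaves the plan unchanged but is audited", {
  plan <- medication_plan("p1", bb_step = 2)
  sched <- build_schedule(d0)
  win <- clean_window(sched$due_date[1]); win$heart_rate[3] <- 55
  q <- assess_window(win, sched$due_date[1], 80)
  p <- classify_proposal(sched[1, ], q, plan,
                         symptoms = symptom_report("p1", sched$due_date[1]))
  expect_equal(p$outcome, "NURSE_EVAL_ABERRANT_VITALS")
  r <- apply_review(p, "CONTACT_PATIENT_THEN_DECIDE", plan,
                    final_decision = "hold")
  expect_equal(current_dose(r$plan, "beta_blocker"), 2.5)
  expect_equal(r$audit$nurse_action, "CONTACT_PATIENT_THEN_DECIDE")
  expect_equal(r$audit$final_decision, "hold")
  expect_null(r$notification)
  expect_error(apply_review(p, "CONTACT_PATIENT_THEN_DECIDE", plan),
               "final_decision")
})

test_that("uptitrating past the guideline maximum is a hard error", {
  plan <- medication_plan("p1", bb_step = 6)  # bisoprolol 10 mg, the cap
  p <- structure(list(patient_id = "p1", due_date = d0 + 14,
                      drug_class = "beta_blocker", sequence_index = 1L,
                      outcome = "UPTITRATE", evidence = list()),
                 class = "proposal")
  expect_error(apply_review(p, "CONFIRM", plan), "safety violation")
  # and never silently clamped
  expect_equal(current_dose(plan, "beta_blocker"), 10)
})

test_that("optimal-reached freezes the drug class", {
  plan <- medication_plan("p1", bb_step = 6)
  sched <- build_schedule(d0)
  e <- make_clean_evidence()
  p <- classify_proposal(sched[1, ], e$quality, plan, symptoms = e$symptoms)
  expect_equal(p$outcome, "NO_UPTITRATION")
  r <- apply_review(p, "OPTIMAL_REACHED", plan)
  expect_true(r$plan$drugs$beta_blocker$at_optimal)
  # later proposals for that class are NO_UPTITRATION regardless of evidence
  plan2 <- r$plan
  plan2$drugs$beta_blocker$current_step_index <- 2L
  p2 <- classify_proposal(sched[3, ], e$quality, plan2, symptoms = e$symptoms)
  expect_equal(p2$outcome, "NO_UPTITRATION")
})

test_that("daily plan push reports doses and flags changes", {
  plan <- medication_plan("p1", bb_step = 2)
  m1 <- daily_plan_push(plan, d0)
  expect_false(m1$changed)
  expect_equal(m1$doses$beta_blocker, 2.5)
  expect_equal(m1$doses$diuretic, "monitored")  # present, never titrated

  plan$drugs$beta_blocker$current_step_index <- 3L
  m2 <- daily_plan_push(plan, d0 + 1, previous = m1)
  expect_true(m2$changed)
  expect_true(m2$requires_confirmation)
  m3 <- daily_plan_push(plan, d0 + 2, previous = m2)
  expect_false(m3$changed)
})
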