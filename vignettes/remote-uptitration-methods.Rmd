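---
title: "Methods: rule-based remote uptitration and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based remote uptitration and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uptitrate)
```

## The problem

Guidelines for heart failure with reduced ejection fraction call for
stepwise uptitration of a beta-blocker and an ACE inhibitor (or ARB) to
the maximum tolerated, evidence-based daily dose, guided by the
patient's weight, blood pressure, heart rate and kidney function. In
practice many patients remain on suboptimal doses because dose changes
happen only at occasional clinic visits. A remote follow-up system
moves this loop into daily life: home sensors transmit vitals every
day, the patient confirms medication intake on a smartphone, a rules
engine screens the accumulating data, proposes the next dose step at
fixed biweekly moments, and a heart-failure nurse reviews every
proposal before anything reaches the patient's phone.

`uptitrate` implements that server-side workflow as small, pure,
testable components, plus a synthetic cohort simulator so the entire
pipeline can be exercised and validated with no patient data.

## Threshold monitoring

Each day's sample is checked against fixed thresholds
(`threshold_set()`): weight at or above baseline + 2 kg, heart rate
outside (60, 100) bpm, systolic pressure outside (90, 160) mm Hg,
diastolic outside (60, 95) mm Hg. Heart-rate and pressure bounds are
strict inequalities, matching the clinical convention of alerting only
beyond the printed bound; the weight rule is inclusive because the
alarm level is itself the 2 kg gain. The baseline weight is the
enrollment-day weight and is never updated automatically — silent
rebaselining would mask gradual fluid retention.

An alert requires the *same* parameter to cross on `run_length = 3`
consecutive calendar days, each day having a valid measurement of that
parameter. A measured in-range day or a missing day breaks the run.
This same-parameter, no-gaps reading is deliberately conservative: a
mixture rule (any parameter crossing on 3 consecutive days) would fire
on unrelated one-off deviations, and counting unmeasured days as
"still crossing" would alert on absent evidence. One alert is emitted
per maximal run — it fires on the third day and does not re-fire while
the crossing continues, so a week-long bradycardia produces one review
task, not five. `detect_sustained()` is verified against a brute-force
scan over every contiguous 3-day window on random streams.

On alert, the symptom questionnaire goes to the patient immediately
(dated the run end) and a review task is opened for the clinical call
center; tasks arising on a weekend become visible on Monday
(`work_calendar()`, default Mon–Fri 08:00–17:00 — the sources say only
"working hours", so both the days and the hours are configurable).

## The scheduled-action lifecycle

Every daily obligation — confirm each medication intake, measure
vitals, answer a questionnaire — is a `scheduled_action()` with a
5-hour window: one hour before to four hours after the ideal time. The
lifecycle is a small state machine:

* first in-window app response wins (`confirmed_app` /
  `declined_app`); later or out-of-window responses are ignored;
* unresolved at ideal + 2 h: one reminder push;
* unresolved at window close: a *no-registration* tag, then a
  technical call-center task due within 12 h of the close, deferred to
  the next working instant when the calendar is closed. The call
  resolves the action to `confirmed_callcenter`,
  `declined_callcenter`, or — vitals and questionnaires only —
  `no_recording`.

Every action therefore ends in exactly one terminal ledger entry, and
category counts always sum to the number of scheduled actions — the
conservation property the adherence accounting relies on. Adherence is
the share of actions eventually confirmed, app or phone, reported at
two decimals with half-up rounding (base R's `round()` is
half-to-even, which disagrees with how clinical tables are printed).
Per-patient call statistics use linear-interpolation quartiles
(`stats::quantile()` type 7) so small worked examples are exactly
reproducible.

## The titration engine

`build_schedule()` generates proposal events every 14 days starting at
enrollment + 14, alternating beta-blocker first, for the 91-day active
phase — six proposals, with a kidney-function blood request seven days
before each ACE-I event and a short symptom questionnaire before every
event. After the active phase the engine generates nothing
automatically; the monitoring continues and a manual proposal can
still be classified and reviewed through the same functions.

`classify_proposal()` is a pure function of the evidence snapshot; the
cascade is evaluated in a fixed, documented order and the first match
wins:

1. at the top ladder step, or optimal declared → `NO_UPTITRATION`;
2. window completeness `< 0.8`, or questionnaire missing →
   `NURSE_EVAL_INCOMPLETE`;
3. any crossing or sustained alert in the 14-day window →
   `NURSE_EVAL_ABERRANT_VITALS`;
4. ACE-I only: blood missing or older than 14 days →
   `NURSE_EVAL_INCOMPLETE`; eGFR `< 30` mL/min/1.73 m² or a drop of
   more than 25 % from the enrollment baseline →
   `NURSE_EVAL_ABERRANT_BLOOD`;
5. any symptom red flag → `NURSE_EVAL_ABERRANT_VITALS`;
6. otherwise → `UPTITRATE`.

The published outcome taxonomy names the three nurse-evaluation
families but not the thresholds behind them, so the completeness
cutoff (0.8 of 14 expected days), the renal rules (absolute floor 30,
relative drop 25 %, 14-day staleness) and the ordering are this
package's own reconstruction, chosen to reproduce the design's stated
large safety margin: anything suspicious routes to the nurse rather
than to an automatic refusal or an automatic dose change. Two
consequences are enforced by construction and tested as invariants: an
`UPTITRATE` outcome can never coexist with an active crossing, and no
plan can ever exceed the guideline maximum daily dose — `apply_review()`
raises a safety-violation error rather than clamping.

Dose ladders end exactly at the guideline maxima (bisoprolol 10 mg,
nebivolol 5, enalapril/ramipril/perindopril 10, lisinopril 20,
candesartan 16, losartan 100). Only the maxima are fixed by guideline;
the intermediate steps follow common European titration practice
(start low, roughly double per step) and are configurable. Diuretics
are carried on the plan for adherence monitoring but are never
titrated by the engine.

Every review is appended to an immutable audit record; a dose change
emits a pop-up notification the patient must confirm, and the daily
plan push (`daily_plan_push()`) flags exactly the mornings on which
anything changed.

## The synthetic cohort

The simulator exists to give every module statistically realistic
input at desk scale. Defaults are the study conditions of a small
heart-failure uptitration cohort: 14 patients followed 182 days;
baseline heart rate 73 (SD 13) bpm, systolic 112 (14), diastolic
75 (12) mm Hg, eGFR 50 (28) mL/min/1.73 m², all truncated to
physiologic ranges. Baseline weight is not published for that cohort —
only BMI 28 (5) — so the generator draws weight around 81 kg (SD 15),
BMI 28 at average stature. Engagement defaults follow the observed
ledger shares: in-window app confirmation 0.77, in-app decline 0.03,
device transmission failure 0.13; the phone-confirmation probability
0.75 makes most escalated actions resolve as call-center
confirmations, mirroring the observed dominance of phone-recovered
intakes.

Vitals are baseline + a linear-in-step, immediate dose response
(defaults: −2 bpm and −2 mm Hg systolic per beta-blocker step; −3/−2
mm Hg per ACE-I step) + Gaussian daily noise. This is deliberately
non-physiological — no pharmacokinetics, no lag, no adaptation — but
sufficient to exercise the threshold logic: a strong configured dose
response reliably drives sustained bradycardia and shifts proposals
into the nurse-evaluation outcomes. Technical failures withhold the
device sample but leave it recoverable by phone, so vitals either
arrive as `device_auto` or `callcenter_phone`, or end as
`no_recording`.

Randomness is reproducible by construction: one integer seed, with
per-patient substreams derived deterministically from
(seed, patient index), so a fixed seed reruns the full pipeline —
event log, ledger, report — byte-identically, and profiles do not
change when the cohort is reordered or resized upward.

What passing simulator-based tests shows is internal consistency:
configured probabilities are recovered from the ledger within binomial
confidence intervals, configured dose-response slopes are recovered by
regression within two standard errors, and the engine's safety
invariants hold over many seeded cohorts. It does not show clinical
validity on real patients — real vitals are autocorrelated,
engagement decays over time, and dropout, hospitalisation and
co-medication are all outside the generator's scope.

## Numerical and design choices

* **Rounding.** All printed percentages use half-up rounding at the
  precision of the corresponding report table (0 dp for proposal and
  nurse-action shares, 2 dp for adherence).
* **Quantiles.** Type 7 (linear interpolation), stated so examples are
  reproducible.
* **Degenerate inputs.** An empty ledger yields a defined report with
  `NA` percentages and no division; an empty event log reports zero
  counts; a sample with all vitals missing is rejected at
  construction.
* **Tie-breaks.** The classification cascade is first-match-wins in
  the documented order; duplicate in-window responses resolve to the
  first; duplicate alert dispatch is an idempotency error rather than
  a silent de-duplication.
* **Problem sizes.** The test suite runs cohorts of 1–3 patients over
  2–13 weeks and property loops of 25–100 replicates; the
  five-thousand-action recovery check and the hundred-cohort safety
  sweep are the largest cases, chosen to give tight intervals while
  keeping the suite fast on one CPU.

## Known limitations

The decision cascade is a faithful reconstruction of the published
outcome families, not the original (unpublished) decision trees; the
short symptom questionnaire is represented by generic red-flag
booleans because its items are not public. Call batching is not
modelled — every escalated action places its own call, so simulated
call totals exceed what a human call center that batches several
missed actions into one phone call would log. The less-intensive
follow-up phase generates no automatic proposals; nurse-initiated
changes go through `classify_proposal()`/`apply_review()` manually.
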