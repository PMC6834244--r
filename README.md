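# uptitrate

A rules engine and synthetic-cohort simulator for **remote heart-failure
medication uptitration**.

Guideline care for heart failure with reduced ejection fraction titrates
a β-blocker and an ACE inhibitor (or ARB) stepwise to the maximum
tolerated daily dose, guided by weight, blood pressure, heart rate and
kidney function (eGFR). `uptitrate` implements the server side of a
two-way remote follow-up workflow that supports this process:

* **Telemetry monitoring** — daily vital samples are checked against
  thresholds (weight ≥ baseline + 2 kg; HR outside (60, 100) bpm; SBP
  outside (90, 160) mm Hg; DBP outside (60, 95) mm Hg); the same
  parameter crossing on **3 consecutive measured days** raises one
  sustained alert, pushing a symptom questionnaire to the patient and a
  review task to the clinical call center (weekend tasks become visible
  Monday).
* **Engagement lifecycle** — every scheduled action (medication intake,
  vital measurement, questionnaire) has a 5-hour window (−1 h/+4 h around
  the ideal time), a reminder at +2 h, a *no-registration* tag at window
  close, and call-center escalation within 12 h during working hours.
  Each action resolves to exactly one ledger outcome; adherence is
  `(confirmed_app + confirmed_callcenter) / total`.
* **Titration engine** — biweekly proposals alternating β-blocker/ACE-I
  starting at enrollment + 14 days over a 91-day active phase (6
  proposals; blood withdrawal requested 7 days before each ACE-I event).
  A fixed first-match rule cascade classifies each proposal as
  `UPTITRATE`, `NO_UPTITRATION`, or nurse evaluation for incomplete
  data, aberrant vitals, or aberrant blood values. Every proposal is
  nurse-reviewed; dose ladders are hard-capped at the guideline maxima
  (e.g. bisoprolol 10 mg, enalapril 10 mg, lisinopril 20 mg, losartan
  100 mg).
* **Cohort simulator** — reproducible synthetic patients (baselines,
  adherence behaviour, dose response, technical failures) so the whole
  pipeline runs end-to-end with no patient data.
* **Reporting** — adherence tables, proposal/nurse-action distributions,
  call-center statistics and dose-census summaries, as JSON/CSV/JSONL.

## Worked example

```r
library(uptitrate)

# one day's sample: bradycardia below the 60 bpm bound
s <- vital_sample("p1", "2026-01-07", heart_rate = 55, systolic = 120)
evaluate_sample(s, baseline_weight = 80)
#> # A tibble: 1 × 5
#>   patient_id date       parameter  direction value
#>   <chr>      <date>     <chr>      <chr>     <dbl>
#> 1 p1         2026-01-07 heart_rate low          55

# simulate 14 patients over the 91-day active phase and report
res <- run_cohort(sim_config(n_patients = 14, n_days = 91, seed = 7))
res$report
#> <run_report>
#>   proposals: 84 total, 24 conclusive (29%)
#>   outcome                    count percent
#> 1 UPTITRATE                     22      26
#> 2 NO_UPTITRATION                 2       2
#> 3 NURSE_EVAL_INCOMPLETE         11      13
#> 4 NURSE_EVAL_ABERRANT_VITALS    44      52
#> 5 NURSE_EVAL_ABERRANT_BLOOD      5       6
#>   ...
```

The 14 simulated patients produce 6 proposals each (84 in total:
alternating drug classes every 14 days). Each proposal's outcome comes
from the rule cascade over that patient's previous 14 days of telemetry,
blood results and questionnaire; here just over half route to the nurse
for aberrant vitals — patients whose (dose-lowered) heart rate or
pressure crossed a threshold in the window — and the overall ledger
adherence is 91.19 % (4647/5096 scheduled actions confirmed in-app or by
phone). A safety invariant holds by construction: no proposal ever
uptitrates past a ladder's guideline maximum, and no `UPTITRATE` outcome
is generated while a threshold crossing is active.

A command-line runner wrapping the same functions is installed at
`inst/cli/uptitrate-cli.R`:

```sh
Rscript inst/cli/uptitrate-cli.R simulate --patients 14 --days 182 --seed 7 --out-dir out/
Rscript inst/cli/uptitrate-cli.R validate-config --config run.yaml
```

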