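Package: uptitrate
Title: Rules Engine and Cohort Simulator for Remote Heart Failure
    Medication Uptitration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A testable implementation of a remote heart-failure
    follow-up workflow: daily vital-sign threshold monitoring with
    sustained (three-consecutive-day) crossing alerts, a scheduled-action
    lifecycle with reminders, no-registration tagging and call-center
    escalation, a semiautomatic beta-blocker/ACE-inhibitor dose-titration
    engine with nurse review and guideline dose caps, an adherence and
    call-center accounting layer, and a synthetic patient-cohort
    simulator so the whole pipeline can be exercised without patient
    data. Includes a command-line runner and reproducible report
    generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
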