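#' Compile a run report
#'
#' Pure function of a run's event record (ledger, proposals, nurse audit,
#' calls, plan history): tallies adherence per stratum, the proposal
#' outcome distribution, nurse responses, call-center statistics and
#' per-patient titration endpoints. Proposal and nurse percentages are
#' reported to 0 decimals, adherence to 2, all half-up.
#'
#' @param sim a `cohort_sim` from [simulate_cohort()], or a list with the
#'   same `ledger`, `proposals`, `audit`, `calls`, `plan_history`,
#'   `plans` elements.
#' @param census_days follow-up days at which the share of patients on
#'   the guideline maximum dose is taken.
#' @return a list of class `run_report` with elements `adherence`,
#'   `proposals`, `nurse_actions`, `calls`, `titration`,
#'   `phase_boundaries`.
#' @export
run_report <- function(sim, census_days = c(91, 182)) {
  adherence <- compute_adherence(sim$ledger)
  pct0 <- function(n, total) {
    if (total == 0) rep(NA_real_, length(n)) else round_half_up(100 * n / total, 0)
  }
  prop_counts <- table(factor(sim$proposals$outcome, levels = proposal_outcomes))
  proposals <- tibble::tibble(
    outcome = names(prop_counts),
    count = as.integer(prop_counts),
    percent = pct0(as.integer(prop_counts), nrow(sim$proposals)))
  conclusive <- sum(sim$proposals$outcome %in% c("UPTITRATE", "NO_UPTITRATION"))
  nurse_counts <- if (!is.null(sim$audit)) {
    table(factor(sim$audit$nurse_action, levels = nurse_actions))
  } else {
    table(factor(character(), levels = nurse_actions))
  }
  nurse <- tibble::tibble(
    action = names(nurse_counts), count = as.integer(nurse_counts),
    percent = pct0(as.integer(nurse_counts),
                   if (is.null(sim$audit)) 0L else nrow(sim$audit)))
  titration <- summarize_titration(sim, census_days = census_days)
  structure(
    list(adherence = adherence, proposals = proposals,
         n_proposals = nrow(sim$proposals),
         conclusive = list(
           count = conclusive,
           percent = pct0(conclusive, nrow(sim$proposals))),
         nurse_actions = nurse, calls = call_center_stats(sim$calls),
         titration = titration,
         phase_boundaries = list(active_phase_days = 91,
                                 followup_days = sim$truth$n_days %||% NA)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  proposals: %d total, %d conclusive (%s%%)\n",
              x$n_proposals, x$conclusive$count,
              format(x$conclusive$percent)))
  print(x$proposals)
  cat("  nurse actions:\n"); print(x$nurse_actions)
  cat(sprintf("  calls: %d total, median %s (IQR %s-%s)\n", x$calls$total,
              format(x$calls$median), format(x$calls$q1), format(x$calls$q3)))
  cat("  adherence:\n"); print(x$adherence$overall)
  invisible(x)
}

#' Share of patients at the guideline maximum dose
#'
#' For each census day, a patient counts as "at max" for a drug class
#' when their ladder position on that day is the top step. Positions are
#' read from the plan-change history: the position on the census day is
#' the last recorded step at or before it (step 1 if no change yet).
#'
#' @param sim a `cohort_sim` (needs `plan_history`, `plans`, `truth`).
#' @param census_days days since enrollment at which to take the census.
#' @return a tibble with columns `census_day`, `drug_class`, `n_at_max`,
#'   `n_patients`, `share`.
#' @export
summarize_titration <- function(sim, census_days = c(91, 182)) {
  plans <- sim$plans
  n <- length(plans)
  enroll <- sim$truth$enrollment_date
  hist <- sim$plan_history
  out <- list()
  for (cd in census_days) {
    census_date <- enroll + cd
    for (cls in c("beta_blocker", "ace_i")) {
      col <- paste0(cls, "_step")
      n_at_max <- 0L
      for (p in plans) {
        top <- length(p$drugs[[cls]]$ladder$steps)
        step_on_day <- 1L
        if (!is.null(hist)) {
          h <- hist[hist$patient_id == p$patient_id & hist$date <= census_date, ]
          if (nrow(h) > 0) step_on_day <- h[[col]][nrow(h)]
        }
        if (step_on_day >= top) n_at_max <- n_at_max + 1L
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        census_day = cd, drug_class = cls, n_at_max = n_at_max,
        n_patients = n, share = if (n > 0) n_at_max / n else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Serialise a run report to JSON
#'
#' Mirrors the structure of the printed adherence/proposal/nurse tables
#' (stratum -> outcome -> count, percent). Byte-identical for identical
#' reports.
#'
#' @param report a [run_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  adh <- function(tbl) {
    lapply(stats::setNames(seq_len(nrow(tbl)), tbl$stratum), function(i) {
      row <- tbl[i, ]
      c(lapply(terminal_outcomes, function(o) row[[o]]) |>
          stats::setNames(terminal_outcomes),
        list(total = row$total, n_adherent = row$n_adherent,
             adherence_pct = row$adherence_pct))
    })
  }
  obj <- list(
    adherence = list(overall = adh(report$adherence$overall),
                     by_kind = adh(report$adherence$by_kind),
                     by_drug = adh(report$adherence$by_drug)),
    proposals = stats::setNames(
      lapply(seq_len(nrow(report$proposals)), function(i)
        list(count = report$proposals$count[i],
             percent = report$proposals$percent[i])),
      report$proposals$outcome),
    conclusive = report$conclusive,
    nurse_actions = stats::setNames(
      lapply(seq_len(nrow(report$nurse_actions)), function(i)
        list(count = report$nurse_actions$count[i],
             percent = report$nurse_actions$percent[i])),
      report$nurse_actions$action),
    calls = list(total = report$calls$total,
                 by_reason = as.list(report$calls$by_reason),
                 median = report$calls$median, q1 = report$calls$q1,
                 q3 = report$calls$q3),
    titration = lapply(seq_len(nrow(report$titration)), function(i)
      as.list(report$titration[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' End-to-end run
#'
#' Simulates a cohort (or consumes file inputs), pipes it through the
#' monitoring, engagement and titration modules, and writes the event
#' log (JSONL), ledger (CSV) and report (JSON) to an output directory.
#' Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory; created if absent. `NULL` skips
#'   writing.
#' @return a list with `sim` (the `cohort_sim`) and `report`
#'   (the [run_report()]), invisibly.
#' @export
run_cohort <- function(config = sim_config(), out_dir = NULL) {
  sim <- simulate_cohort(config)
  report <- run_report(sim)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ledger_csv(sim$ledger, file.path(out_dir, "ledger.csv"))
    write_events_jsonl(sim$events, file.path(out_dir, "events.jsonl"))
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  invisible(list(sim = sim, report = report))
}
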