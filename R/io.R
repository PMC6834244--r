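#' Read daily vital samples from CSV
#'
#' Expected columns: `patient_id`, `date` (ISO-8601), `weight_kg`,
#' `sbp_mmhg`, `dbp_mmhg`, `hr_bpm`, `source`, `recorded_at`. Empty cells
#' are missing values. Malformed rows (non-positive vitals, bad dates,
#' all vitals missing) are rejected row by row with a logged reason; the
#' read continues.
#'
#' @param path CSV file path.
#' @param quiet suppress per-row rejection messages.
#' @return a tibble of samples in the internal column layout
#'   (`patient_id`, `date`, `weight`, `systolic`, `diastolic`,
#'   `heart_rate`, `source`, `recorded_at`), with an attribute
#'   `rejected` holding the rejected row numbers and reasons.
#' @export
read_vitals_csv <- function(path, quiet = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("patient_id", "date", "weight_kg", "sbp_mmhg", "dbp_mmhg",
              "hr_bpm", "source")
  assert_that(all(needed %in% names(raw)),
              paste("missing columns:",
                    paste(setdiff(needed, names(raw)), collapse = ", ")))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  rows <- vector("list", nrow(raw))
  rejected <- list()
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    row <- tryCatch({
      rec <- if (!is.null(r$recorded_at) && nzchar(r$recorded_at))
        as.POSIXct(r$recorded_at, tz = "UTC") else NULL
      vital_sample(r$patient_id, r$date,
                   weight = num(r$weight_kg), systolic = num(r$sbp_mmhg),
                   diastolic = num(r$dbp_mmhg), heart_rate = num(r$hr_bpm),
                   source = if (nzchar(r$source)) r$source else "device_auto",
                   recorded_at = rec)
    }, error = function(e) e)
    if (inherits(row, "error")) {
      msg <- conditionMessage(row)
      rejected[[length(rejected) + 1L]] <- tibble::tibble(row = i, reason = msg)
      if (!quiet) message(sprintf("row %d rejected: %s", i, msg))
    } else {
      rows[[i]] <- row
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- vital_sample("x", Sys.Date(), weight = 1)[0, ]
  }
  attr(out, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else
    tibble::tibble(row = integer(), reason = character())
  out
}

#' Write the adherence ledger to CSV
#'
#' Columns: `patient_id`, `date`, `kind`, `drug`, `outcome`,
#' `resolved_at`.
#'
#' @param ledger ledger tibble (from [lifecycle()] rows or
#'   [simulate_cohort()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(ledger, path) {
  out <- data.frame(
    patient_id = ledger$patient_id,
    date = format(as.Date(ledger$ideal_time, tz = "UTC")),
    kind = ledger$kind, drug = ledger$drug, outcome = ledger$outcome,
    resolved_at = format(ledger$resolved_at, "%Y-%m-%dT%H:%M:%SZ",
                         tz = "UTC"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write events as JSON Lines
#'
#' One JSON object per line with fields `type`, `patient_id`, `date`,
#' `parameter`/`kind` and a payload of the remaining columns, suitable
#' for downstream audit tooling. Deterministic field order, so a fixed
#' seed yields byte-identical output.
#'
#' @param events a tibble of events.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    row <- as.list(events[i, ])
    row <- lapply(row, function(v) {
      if (inherits(v, "POSIXct")) format(v, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      else if (inherits(v, "Date")) format(v)
      else v
    })
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `n_patients`, `n_days`, `seed`, `enrollment_date`,
#' `schedule` (`interval_days`, `active_phase_days`, `first_offset_days`,
#' `blood_lead_days`), `thresholds` (named overrides for
#' [threshold_set()]), `behavior`, `drugs` (list of
#' `{name, class, steps}` ladders).
#'
#' @param path YAML file path.
#' @return a list with `config` (a [sim_config()]), `thresholds`,
#'   `schedule` parameters, `ladders`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- do.call(threshold_set, y$thresholds %||% list())
  ladders <- if (!is.null(y$drugs)) {
    stats::setNames(lapply(y$drugs, function(d)
      dose_ladder(d$name, d$class, d$steps)),
      vapply(y$drugs, function(d) tolower(d$name), character(1)))
  } else default_ladders()
  args <- list()
  for (k in c("n_patients", "n_days", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$enrollment_date)) args$enrollment_date <- as.Date(y$enrollment_date)
  if (!is.null(y$behavior)) args$behavior <- utils::modifyList(
    sim_config()$behavior, y$behavior)
  cfg <- do.call(sim_config, args)
  sched <- utils::modifyList(
    list(interval_days = 14, active_phase_days = 91, first_offset_days = 14,
         blood_lead_days = 7),
    y$schedule %||% list())
  list(config = cfg, thresholds = th, schedule = sched, ladders = ladders)
}
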