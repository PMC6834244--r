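# Shared fixture builders. Everything is generated in code; no stored data.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")
d0 <- as.Date("2026-01-05")  # a Monday

make_sample <- function(date, hr = NA, sbp = NA, dbp = NA, wt = NA,
                        pid = "p1") {
  vital_sample(pid, date, weight = wt, systolic = sbp, diastolic = dbp,
               heart_rate = hr)
}

# crossing/measurement pattern for one parameter over consecutive dates:
# status per day is "cross", "normal" (measured, in range) or NA (missing)
pattern_history <- function(status, parameter = "heart_rate", start = d0,
                            pid = "p1") {
  dates <- start + seq_along(status) - 1
  measured <- tibble::tibble(date = dates[!is.na(status)],
                             parameter = parameter)
  cross_dates <- dates[!is.na(status) & status == "cross"]
  crossings <- tibble::tibble(
    patient_id = rep(pid, length(cross_dates)), date = cross_dates,
    parameter = rep(parameter, length(cross_dates)),
    direction = rep("low", length(cross_dates)),
    value = rep(55, length(cross_dates)))
  list(crossings = crossings, measured = measured)
}

# independent oracle: scan every contiguous k-day window; keep windows whose
# start is the start of a maximal run (previous day not a crossing day)
brute_force_alerts <- function(crossings, k = 3) {
  out <- list()
  for (param in unique(crossings$parameter)) {
    days <- sort(crossings$date[crossings$parameter == param])
    for (s in days) {
      s <- as.Date(s, origin = "1970-01-01")
      window <- s + 0:(k - 1)
      if (all(window %in% days) && !((s - 1) %in% days)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          patient_id = crossings$patient_id[1], parameter = param,
          run_start = s, run_end = s + k - 1)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(patient_id = character(), parameter = character(),
                          run_start = as.Date(character()),
                          run_end = as.Date(character())))
  }
  res <- do.call(rbind, out)
  res[order(res$run_end, res$parameter), ]
}

# a fully-measured clean window of n days before `due`
clean_window <- function(due, n = 14, hr = 75, sbp = 120, dbp = 80, wt = 80,
                         pid = "p1") {
  do.call(rbind, lapply(seq_len(n), function(i)
    make_sample(due - i, hr = hr, sbp = sbp, dbp = dbp, wt = wt, pid = pid)))
}

# a ledger built from outcome counts
ledger_from_counts <- function(counts, kind = "medication_intake",
                               drug = NA_character_) {
  tibble::tibble(
    patient_id = "p1", kind = kind, drug = drug,
    ideal_time = ts_utc("2026-01-05 08:00:00"),
    outcome = as.character(rep(names(counts), counts)),
    resolved_at = ts_utc("2026-01-05 09:00:00"))
}
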