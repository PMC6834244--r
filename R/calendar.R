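#' Working calendar for call-center availability
#'
#' Both the clinical and the technical call center operate only during
#' working hours; notifications arriving outside them (evenings, weekends)
#' are handled at the next working instant. The default calendar is
#' Monday-Friday, 08:00-17:00.
#'
#' @param working_days integer vector of ISO weekdays (1 = Monday ...
#'   7 = Sunday) on which the call centers are staffed.
#' @param start_hour first staffed hour of the day (0-23).
#' @param end_hour end of the staffed interval (exclusive, 1-24).
#' @return an object of class `work_calendar`.
#' @export
#' @examples
#' cal <- work_calendar()
#' next_working_time(cal, as.POSIXct("2026-01-03 12:00", tz = "UTC")) # Saturday
work_calendar <- function(working_days = 1:5, start_hour = 8, end_hour = 17) {
  working_days <- sort(unique(as.integer(working_days)))
  assert_that(length(working_days) > 0 && all(working_days %in% 1:7),
              "working_days must be a non-empty subset of 1..7")
  assert_that(start_hour >= 0 && end_hour <= 24 && start_hour < end_hour,
              "working hours must satisfy 0 <= start < end <= 24")
  structure(
    list(working_days = working_days, start_hour = start_hour,
         end_hour = end_hour),
    class = "work_calendar"
  )
}

#' @export
print.work_calendar <- function(x, ...) {
  days <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  cat(sprintf("<work_calendar> %s, %02d:00-%02d:00\n",
              paste(days[x$working_days], collapse = ","),
              x$start_hour, x$end_hour))
  invisible(x)
}

iso_weekday <- function(t) as.integer(format(t, "%u"))

#' Is a calendar day a working day?
#'
#' @param calendar a [work_calendar()].
#' @param date a `Date` (or coercible).
#' @return logical vector.
#' @export
is_working_day <- function(calendar, date) {
  iso_weekday(as.Date(date)) %in% calendar$working_days
}

#' Does an instant fall within working hours?
#'
#' @param calendar a [work_calendar()].
#' @param time a `POSIXct` instant.
#' @return logical vector.
#' @export
is_working_time <- function(calendar, time) {
  hr <- as.numeric(format(time, "%H")) + as.numeric(format(time, "%M")) / 60 +
    as.numeric(format(time, "%S")) / 3600
  iso_weekday(time) %in% calendar$working_days &
    hr >= calendar$start_hour & hr < calendar$end_hour
}

#' First working instant at or after a given time
#'
#' Used to defer call-center tasks: a task due Saturday noon is placed at
#' the opening of the next working day (Monday 08:00 by default).
#'
#' @param calendar a [work_calendar()].
#' @param time a scalar `POSIXct` due instant.
#' @return a `POSIXct` instant, `>= time`, inside working hours.
#' @export
next_working_time <- function(calendar, time) {
  assert_that(length(time) == 1L, "time must be a scalar instant")
  if (is_working_time(calendar, time)) return(time)
  day <- as.Date(time, tz = attr(time, "tzone") %||% "UTC")
  open_today <- as.POSIXct(paste0(format(day), sprintf(" %02d:00:00", calendar$start_hour)),
                           tz = attr(time, "tzone") %||% "UTC")
  if (is_working_day(calendar, day) && time < open_today) return(open_today)
  repeat {
    day <- day + 1
    if (is_working_day(calendar, day)) {
      return(as.POSIXct(paste0(format(day), sprintf(" %02d:00:00", calendar$start_hour)),
                        tz = attr(time, "tzone") %||% "UTC"))
    }
  }
}

#' First working day at or after a date
#'
#' @param calendar a [work_calendar()].
#' @param date a `Date`.
#' @return a `Date` on which the calendar is staffed.
#' @export
next_working_day <- function(calendar, date) {
  date <- as.Date(date)
  while (!is_working_day(calendar, date)) date <- date + 1
  date
}
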