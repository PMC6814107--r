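#' @useDynLib rtflowsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

MIN_PER_DAY <- 1440L

#' Simulation time utilities
#'
#' Simulation time is kept as integer minutes since a configurable origin,
#' which is always a Monday at 00:00. All durations used by the department
#' model (25/45/60/120/960-minute tasks, multi-day lags, week-long planned
#' delays) are exact multiples of one minute, so integer minutes avoid any
#' floating-point drift in schedules. Day boundaries fall at 00:00; day 0 is
#' the origin Monday.
#'
#' @param day simulation day index (0 = origin Monday).
#' @param hour,minute time of day.
#' @return `sim_time()` returns minutes since origin; `sim_day()`,
#'   `sim_tod()` and `sim_weekday()` decompose a minute stamp into day index,
#'   minute-of-day and weekday index (1 = Monday ... 7 = Sunday).
#' @examples
#' sim_time(1, 8, 30)          # Tuesday 08:30
#' sim_weekday(sim_time(1, 8)) # 2
#' @export
sim_time <- function(day, hour = 0L, minute = 0L) {
  as.integer(day) * MIN_PER_DAY + as.integer(hour) * 60L + as.integer(minute)
}

#' @rdname sim_time
#' @param t simulation time in minutes since origin.
#' @export
sim_day <- function(t) t %/% MIN_PER_DAY

#' @rdname sim_time
#' @export
sim_tod <- function(t) t %% MIN_PER_DAY

#' @rdname sim_time
#' @export
sim_weekday <- function(t) (t %/% MIN_PER_DAY) %% 7L + 1L

#' @rdname sim_time
#' @export
day_weekday <- function(day) day %% 7L + 1L

WEEKDAY_NAMES <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

#' Convert between simulation days and calendar dates
#'
#' @param day simulation day index (0-based).
#' @param origin calendar date of simulation day 0; must be a Monday.
#' @return a `Date` for `sim_date()`; an integer day index for
#'   `as_sim_day()`.
#' @export
sim_date <- function(day, origin = "2017-01-02") {
  origin <- as.Date(origin)
  stopifnot("origin must be a Monday" = format(origin, "%u") == "1")
  origin + day
}

#' @rdname sim_date
#' @param date a calendar `Date` (or string coercible to one).
#' @export
as_sim_day <- function(date, origin = "2017-01-02") {
  origin <- as.Date(origin)
  stopifnot("origin must be a Monday" = format(origin, "%u") == "1")
  as.integer(as.Date(date) - origin)
}

#' Format a simulation minute stamp as ISO-8601
#'
#' Used by the event-log writer.
#' @param t minutes since origin.
#' @param origin calendar date of day 0.
#' @export
format_sim_time <- function(t, origin = "2017-01-02") {
  d <- sim_date(sim_day(t), origin)
  sprintf("%sT%02d:%02d:00", format(d, "%Y-%m-%d"),
          sim_tod(t) %/% 60L, sim_tod(t) %% 60L)
}

#' Working-day predicates
#'
#' The department operates Monday to Friday outside the configured public
#' holidays; there are no weekend arrivals or bookings.
#'
#' @param day simulation day index (vectorised).
#' @param holidays integer vector of holiday day indices.
#' @export
is_workday <- function(day, holidays = integer()) {
  day_weekday(day) <= 5L & !(day %in% holidays)
}

#' @rdname is_workday
#' @export
next_workday <- function(day, holidays = integer()) {
  d <- day + 1L
  while (!is_workday(d, holidays)) d <- d + 1L
  d
}

#' Add working minutes to a time stamp
#'
#' Walks forward through working days, counting only minutes inside the
#' working window `[win_start, win_end)` minutes-of-day. Used for treatment
#' planning tasks, which are software-driven and resume the next working
#' morning when they do not fit in the remaining workday.
#'
#' @param t start time (minutes since origin).
#' @param dur working minutes to add (positive).
#' @param win_start,win_end working window as minutes-of-day.
#' @param holidays holiday day indices.
#' @return completion time in minutes since origin.
#' @export
add_working_minutes <- function(t, dur, win_start = 480L, win_end = 1020L,
                                holidays = integer()) {
  stopifnot(dur > 0, win_end > win_start)
  day <- sim_day(t)
  # clamp the cursor into the working window of a working day
  if (!is_workday(day, holidays) || sim_tod(t) >= win_end) {
    day <- next_workday(day, holidays)
    t <- sim_time(day) + win_start
  } else if (sim_tod(t) < win_start) {
    t <- sim_time(day) + win_start
  }
  remaining <- as.integer(dur)
  repeat {
    avail <- sim_time(sim_day(t)) + win_end - t
    if (remaining <= avail) return(t + remaining)
    remaining <- remaining - avail
    day <- next_workday(sim_day(t), holidays)
    t <- sim_time(day) + win_start
  }
}
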