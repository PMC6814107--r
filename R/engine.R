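#' Create a discrete-event simulation engine
#'
#' The engine holds a clock (integer minutes since the origin Monday), an
#' event calendar and a table of event handlers. Events are totally ordered
#' by `(time, priority, insertion sequence)`; the sequence number is a
#' monotone tie-breaker, so processing order is strict and reproducible.
#' Lower priority values fire first at equal times; by convention
#' resource-release events use a lower tier than resource-request events so
#' freed capacity is visible to requests at the same instant.
#'
#' @param origin calendar date of simulation day 0 (a Monday).
#' @param trace logical; when `TRUE` every processed event is appended to an
#'   in-memory log retrievable with [event_log()].
#' @return an engine object (environment) to pass to [schedule_event()],
#'   [set_handler()] and [run_until()].
#' @examples
#' eng <- sim_engine()
#' set_handler(eng, "ping", function(eng, payload, time) NULL)
#' schedule_event(eng, 10, "ping")
#' run_until(eng, 100)
#' @export
sim_engine <- function(origin = "2017-01-02", trace = FALSE) {
  eng <- new.env(parent = emptyenv())
  eng$clock <- 0L
  eng$heap <- heap_new()
  eng$handlers <- list()
  eng$kind_names <- character()
  eng$payload_env <- new.env(hash = TRUE, parent = emptyenv())
  eng$origin <- origin
  eng$trace <- isTRUE(trace)
  eng$log_t <- numeric()
  eng$log_kind <- character()
  eng$log_pid <- integer()
  eng$log_res <- character()
  eng$log_n <- 0L
  class(eng) <- "sim_engine"
  eng
}

#' @export
print.sim_engine <- function(x, ...) {
  cat(sprintf("<sim_engine> clock = %s, %d pending event(s)\n",
              format_sim_time(x$clock, x$origin), heap_size(x$heap)))
  invisible(x)
}

#' Schedule, cancel and inspect events
#'
#' `schedule_event()` places an event on the calendar and returns a handle
#' that can be passed to `cancel_event()`. Scheduling strictly before the
#' current clock is a logic bug and raises an error. Cancellation marks the
#' event dead in O(1); a cancelled event never fires.
#'
#' @param eng engine from [sim_engine()].
#' @param time event time, minutes since origin; must be `>=` the clock.
#' @param kind event label; dispatched to the handler registered under the
#'   same name.
#' @param payload opaque value handed to the handler.
#' @param priority integer tier; lower fires first at equal times.
#' @return an integer event handle.
#' @export
schedule_event <- function(eng, time, kind, payload = NULL, priority = 5L) {
  if (time < eng$clock) {
    stop(sprintf("logic bug: scheduling '%s' at t=%s before clock t=%s",
                 kind, time, eng$clock))
  }
  k <- match(kind, eng$kind_names)
  if (is.na(k)) {
    eng$kind_names <- c(eng$kind_names, kind)
    k <- length(eng$kind_names)
  }
  # scalar numeric payloads (patient ids, day indices) live in the heap
  # itself; anything else goes into a hash keyed by event id
  scalar <- is.numeric(payload) && length(payload) == 1L && !is.nan(payload)
  id <- heap_push(eng$heap, as.double(time), as.integer(priority),
                  as.integer(k), if (scalar) as.double(payload) else NaN)
  if (!scalar && !is.null(payload)) {
    assign(as.character(id), payload, envir = eng$payload_env)
  }
  invisible(id)
}

#' @rdname schedule_event
#' @param handle handle returned by `schedule_event()`.
#' @return `cancel_event()` returns `TRUE` if the event was pending.
#' @export
cancel_event <- function(eng, handle) {
  heap_cancel(eng$heap, as.integer(handle))
}

#' @rdname schedule_event
#' @export
event_pending <- function(eng, handle) heap_is_alive(eng$heap, handle)

#' Register an event handler
#'
#' @param eng engine.
#' @param kind event label.
#' @param fn `function(eng, payload, time)`.
#' @export
set_handler <- function(eng, kind, fn) {
  eng$handlers[[kind]] <- fn
  invisible(eng)
}

log_event <- function(eng, time, kind, pid = NA_integer_, res = NA_character_) {
  n <- eng$log_n + 1L
  eng$log_t[n] <- time
  eng$log_kind[n] <- kind
  eng$log_pid[n] <- pid
  eng$log_res[n] <- res
  eng$log_n <- n
  invisible(NULL)
}

#' Run the engine
#'
#' Processes events in `(time, priority, sequence)` order until the calendar
#' is exhausted or the next event lies beyond `horizon`; the clock finishes
#' at `horizon`. A handler error aborts the run with the offending event
#' attached to the message.
#'
#' @param eng engine.
#' @param horizon stop time in minutes since origin.
#' @return number of events processed, invisibly.
#' @export
run_until <- function(eng, horizon) {
  count <- 0L
  heap <- eng$heap
  pidkinds <- c("arrive", "contour_ready", "treat_start", "contour_done",
                "plan_done")
  repeat {
    ev <- heap_pop_le(heap, horizon)
    if (!length(ev)) break
    id <- ev[1]
    t <- ev[2]
    kind <- eng$kind_names[ev[3]]
    payload <- ev[4]
    if (is.nan(payload)) {
      key <- as.character(id)
      payload <- get0(key, envir = eng$payload_env, inherits = FALSE)
      if (!is.null(payload)) rm(list = key, envir = eng$payload_env)
    }
    eng$clock <- t
    if (eng$trace) {
      pid <- NA_integer_; res <- NA_character_
      if (is.list(payload)) {
        if (!is.null(payload$pid)) pid <- payload$pid
        if (!is.null(payload$res)) res <- payload$res
      } else if (is.numeric(payload) && length(payload) == 1L &&
                 kind %in% pidkinds) {
        pid <- as.integer(payload)
      }
      log_event(eng, t, kind, pid, res)
    }
    h <- eng$handlers[[kind]]
    if (is.null(h)) stop(sprintf("no handler for event kind '%s'", kind))
    tryCatch(h(eng, payload, t), error = function(e) {
      stop(sprintf("handler error at t=%s for event '%s' (id %d): %s",
                   format_sim_time(t, eng$origin), kind, id,
                   conditionMessage(e)), call. = FALSE)
    })
    count <- count + 1L
  }
  if (is.finite(horizon) && horizon > eng$clock) eng$clock <- horizon
  invisible(count)
}

#' Retrieve or write the event log
#'
#' With tracing enabled the engine records one row per processed event:
#' ISO-8601 time stamp, event kind, patient id and resource id (when the
#' payload carries them). `write_event_log()` serialises the log as JSON
#' Lines or CSV with the same columns.
#'
#' @param eng engine run with `trace = TRUE`.
#' @return a data.frame with columns `time`, `kind`, `patient`, `resource`.
#' @export
event_log <- function(eng) {
  n <- eng$log_n
  data.frame(
    time = if (n) format_sim_time(eng$log_t[seq_len(n)], eng$origin) else character(),
    minutes = eng$log_t[seq_len(n)],
    kind = eng$log_kind[seq_len(n)],
    patient = eng$log_pid[seq_len(n)],
    resource = eng$log_res[seq_len(n)],
    stringsAsFactors = FALSE
  )
}

#' @rdname event_log
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @export
write_event_log <- function(eng, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  log <- event_log(eng)
  if (format == "csv") {
    utils::write.csv(log[c("time", "kind", "patient", "resource")], path,
                     row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(log))) {
      writeLines(jsonlite::toJSON(
        list(time = log$time[i], kind = log$kind[i],
             patient = log$patient[i], resource = log$resource[i]),
        auto_unbox = TRUE, na = "null"), con)
    }
  }
  invisible(path)
}
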