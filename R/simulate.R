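#' Simulate one replication of the pre-treatment workflow
#'
#' Runs the complete department model on the event engine: weekday Poisson
#' arrivals with care content drawn from the catalogue, imaging booked into
#' labeled slot calendars at consultation (Moment 1), lognormal image
#' post-processing lags, contouring dispatched to specialty doctors and
#' treatment planning to skill-matched planning RTTs on an earliest-due-date
#' basis, pull patients pre-scheduled at consultation with daily rebook
#' checks, push patients scheduled at planning start (Moment 2).
#'
#' @param config an `rt_config`.
#' @param seed base seed; combined with `replication` to seed every stream.
#' @param replication replication index.
#' @param warmup_days,horizon_days override the experiment section of the
#'   config (warm-up days discarded by the KPI layer, measured days after).
#' @param trace record an event log (slower; for audits and debugging).
#' @param arrivals_override optional data.frame with columns `day` and
#'   `site`: use these arrivals instead of Poisson draws (deterministic
#'   micro-scenarios and capacity experiments).
#' @return an `rt_sim` object: `patients` (one row per generated patient
#'   with care content, milestone times in minutes and day-level outcomes),
#'   the horizon settings, and the event log when traced.
#' @examples
#' \donttest{
#' sim <- simulate_rt(default_config(), seed = 1, warmup_days = 0,
#'                    horizon_days = 30)
#' head(sim$patients)
#' }
#' @export
simulate_rt <- function(config, seed = 1L, replication = 1L,
                        warmup_days = NULL, horizon_days = NULL,
                        trace = FALSE, arrivals_override = NULL) {
  validate_config(config)
  if (is.null(warmup_days)) warmup_days <- config$experiment$warmup_days
  if (is.null(horizon_days)) horizon_days <- config$experiment$horizon_days
  total_days <- warmup_days + horizon_days
  mat_days <- total_days + config$resources$booking_horizon_days + 30L

  S <- new.env(parent = emptyenv())
  S$cfg <- config
  S$holidays <- as_sim_day(config$holidays, config$origin)
  S$streams <- rng_streams(seed, replication)
  S$eng <- sim_engine(config$origin, trace = trace)
  S$cals <- list(ct = build_slot_calendar(config, "ct", mat_days),
                 mri = build_slot_calendar(config, "mri", mat_days),
                 petct = build_slot_calendar(config, "petct", mat_days))
  S$agendas <- build_agendas(config, mat_days, S$streams$agenda)
  S$team_ids <- split(seq_along(S$agendas),
                      vapply(S$agendas, `[[`, "", "team"))
  S$planners <- build_planner_roster(config)
  S$busy <- integer(nrow(S$planners))
  S$p3_extra <- config$policies$p3_extra_sites
  S$pshift <- config$resources$planners$shift
  S$total_days <- total_days
  S$override <- arrivals_override
  S$pcap <- S$planners$capacity
  S$elig <- list(
    P2 = eligible_planners("P2", S$planners),
    P3 = eligible_planners("P3", S$planners),
    P4 = eligible_planners("P4", S$planners),
    # P4 tasks of sites P3-level planners may take (skill-upgrade scenario)
    P4x = which(S$planners$skill %in% c("P3", "P4")))
  S$plan_min <- lapply(config$care_plans, `[[`, "planning_minutes")
  S$cmin <- vapply(c(acute = "acute", subacute = "subacute",
                     regular = "regular"),
                   function(u) config$service_times$contour[[u]] +
                     config$service_times$peer_review, 0L)

  n_max <- as.integer(ceiling(sum(config$arrivals$weekday_totals) / 5 *
                                total_days * 1.4) + 200L)
  P <- new.env(parent = emptyenv())
  for (f in c("arrival", "ct_end", "last_scan", "ipp_done", "contour_start",
              "contour_done", "plan_start", "plan_done")) {
    P[[f]] <- rep(NA_real_, n_max)
  }
  for (f in c("arrival_day", "delay_weeks", "sched_start_day",
              "actual_start_day", "rebooks", "due_day", "doctor",
              "start_weekday", "start_ev")) {
    P[[f]] <- rep(NA_integer_, n_max)
  }
  for (f in c("site", "plan", "urgency", "strategy", "team",
              "planning_type")) {
    P[[f]] <- rep(NA_character_, n_max)
  }
  for (f in c("mri", "petct", "warping", "image_registration", "beam_setup",
              "combined", "iv_contrast", "palliative")) {
    P[[f]] <- rep(NA, n_max)
  }
  P$rebooks <- rep(0L, n_max)
  P$last_rebook_day <- rep(-1L, n_max)
  P$contour_doc <- rep(NA_integer_, n_max)
  P$planner <- rep(NA_integer_, n_max)
  P$cdur <- rep(NA_integer_, n_max)
  P$pdur <- rep(NA_integer_, n_max)
  P$n <- 0L
  S$P <- P
  S$contour_q <- integer(0)
  S$plan_q <- integer(0)
  S$pending <- integer(0)   # patients with a scheduled, not yet actual, start

  register_handlers(S)

  # day 0 bootstrap
  first <- if (is_workday(0L, S$holidays)) 0L else next_workday(0L, S$holidays)
  schedule_event(S$eng, sim_time(first, 7, 0), "day_start", first,
                 priority = 0L)
  run_until(S$eng, sim_time(total_days) - 1L)

  n <- P$n
  idx <- seq_len(n)
  patients <- data.frame(
    id = idx, site = P$site[idx], plan = P$plan[idx],
    urgency = P$urgency[idx], strategy = P$strategy[idx],
    planning_type = P$planning_type[idx], team = P$team[idx],
    doctor = P$doctor[idx],
    mri = P$mri[idx], petct = P$petct[idx], warping = P$warping[idx],
    image_registration = P$image_registration[idx],
    beam_setup = P$beam_setup[idx], combined = P$combined[idx],
    iv_contrast = P$iv_contrast[idx], palliative = P$palliative[idx],
    delay_weeks = P$delay_weeks[idx], arrival = P$arrival[idx],
    arrival_day = P$arrival_day[idx], ct_end = P$ct_end[idx],
    last_scan = P$last_scan[idx], ipp_done = P$ipp_done[idx],
    contour_start = P$contour_start[idx], contour_done = P$contour_done[idx],
    plan_start = P$plan_start[idx], plan_done = P$plan_done[idx],
    sched_start_day = P$sched_start_day[idx],
    actual_start_day = P$actual_start_day[idx], rebooks = P$rebooks[idx],
    stringsAsFactors = FALSE
  )
  out <- list(patients = patients, warmup_days = warmup_days,
              horizon_days = horizon_days, seed = seed,
              replication = replication,
              log = if (trace) event_log(S$eng) else NULL)
  class(out) <- "rt_sim"
  out
}

#' @export
print.rt_sim <- function(x, ...) {
  cat(sprintf("<rt_sim> %d patients over %d + %d days (seed %s, rep %d)\n",
              nrow(x$patients), x$warmup_days, x$horizon_days, x$seed,
              x$replication))
  invisible(x)
}

national_target <- function(config, urgency) {
  unname(config$targets[urgency])
}

register_handlers <- function(S) {
  eng <- S$eng
  cfg <- S$cfg
  P <- S$P

  set_handler(eng, "day_start", function(eng, payload, t) {
    day <- payload
    # today's doctor availability, flattened for fast dispatch
    ivs <- lapply(S$agendas, doctor_free_intervals, day = day)
    nrows <- vapply(ivs, nrow, 0L)
    S$iv_doc <- rep(seq_along(ivs), nrows)
    flat <- do.call(rbind, ivs)
    S$iv_start <- as.numeric(flat[, 1])
    S$iv_end <- as.numeric(flat[, 2])
    # contouring can only start when a block opens (or a task completes),
    # so earliest-due-date order is decided at those instants
    for (bs in unique(S$iv_start)) {
      schedule_event(eng, bs, "contour_dispatch", NULL, priority = 3L)
    }
    dispatch_contouring_queue(S, t)
    dispatch_planning_queue(S, t)
    # arrivals for today
    wd <- day_weekday(day)
    if (is.null(S$override)) {
      rates <- cfg$arrivals$rate_matrix[, wd]
      counts <- sample_daily_arrivals(wd, rates, S$streams$arrivals)
      sites <- rep(rownames(cfg$arrivals$rate_matrix), counts)
    } else {
      sites <- S$override$site[S$override$day == day]
    }
    ntot <- length(sites)
    if (ntot > 0L) {
      content <- draw_care_content(cfg, sites, S$streams$care_content)
      win <- cfg$arrivals$consult_window
      tods <- with_rng(S$streams$arrivals,
                       sort(win[1] + floor(stats::runif(ntot) *
                                             (win[2] - win[1]))))
      base <- P$n
      idx <- base + seq_len(ntot)
      P$site[idx] <- content$site
      P$plan[idx] <- content$plan
      P$urgency[idx] <- content$urgency
      P$strategy[idx] <- content$strategy
      P$planning_type[idx] <- content$planning_type
      P$team[idx] <- content$team
      P$mri[idx] <- content$mri
      P$petct[idx] <- content$petct
      P$warping[idx] <- content$warping
      P$image_registration[idx] <- content$image_registration
      P$beam_setup[idx] <- content$beam_setup
      P$combined[idx] <- content$combined
      P$iv_contrast[idx] <- content$iv_contrast
      P$palliative[idx] <- content$palliative
      P$delay_weeks[idx] <- content$delay_weeks
      P$start_weekday[idx] <- content$start_weekday
      P$arrival_day[idx] <- day
      P$arrival[idx] <- sim_time(day) + tods
      P$cdur[idx] <- unname(S$cmin[content$urgency])
      P$pdur[idx] <- as.integer(mapply(function(pl, ty) S$plan_min[[pl]][[ty]],
                                       content$plan, content$planning_type))
      for (pid in idx) {
        schedule_event(eng, P$arrival[pid], "arrive", pid, priority = 5L)
      }
      P$n <- base + ntot
    }
    schedule_event(eng, sim_time(day, 17, 30), "checkpoint", day,
                   priority = 8L)
    nxt <- next_workday(day, S$holidays)
    if (nxt < S$total_days) {
      schedule_event(eng, sim_time(nxt, 7, 0), "day_start", nxt,
                     priority = 0L)
    }
  })

  set_handler(eng, "arrive", function(eng, payload, t) {
    pid <- payload
    # doctor of the corresponding specialty, uniform within the team
    ids <- S$team_ids[[P$team[pid]]]
    P$doctor[pid] <- if (length(ids) == 1L) ids else
      with_rng(S$streams$service, ids[sample.int(length(ids), 1L)])
    appt <- book_imaging(
      list(arrival_day = P$arrival_day[pid],
           delay_weeks = P$delay_weeks[pid], urgency = P$urgency[pid],
           iv_contrast = P$iv_contrast[pid], mri = P$mri[pid],
           petct = P$petct[pid]),
      S$cals, clock = t,
      horizon_days = cfg$resources$booking_horizon_days)
    P$ct_end[pid] <- appt$ct$end
    P$last_scan[pid] <- appt$last_scan_end
    ready <- apply_ipp_delays(appt$last_scan_end, P$warping[pid],
                              P$image_registration[pid], cfg,
                              S$streams$ipp)
    P$ipp_done[pid] <- ready
    schedule_event(eng, ready, "contour_ready", pid, priority = 5L)
    if (P$strategy[pid] == "pull") {
      sd <- schedule_start_pull(P$arrival_day[pid], P$urgency[pid],
                                P$delay_weeks[pid], P$start_weekday[pid],
                                cfg, S$streams$ttt, holidays = S$holidays)
      set_start(S, pid, sd)
      P$due_day[pid] <- sd
    } else {
      P$due_day[pid] <- P$arrival_day[pid] +
        national_target(cfg, P$urgency[pid])
    }
  })

  set_handler(eng, "contour_dispatch", function(eng, payload, t) {
    dispatch_contouring_queue(S, t)
  })

  set_handler(eng, "contour_ready", function(eng, payload, t) {
    S$contour_q <- c(S$contour_q, payload)
    dispatch_contouring_queue(S, t)
  })

  set_handler(eng, "contour_done", function(eng, payload, t) {
    pid <- payload
    P$contour_done[pid] <- t
    if (eng$trace) {
      eng$log_res[eng$log_n] <- sprintf("doctor_%d", P$contour_doc[pid])
    }
    S$plan_q <- c(S$plan_q, pid)
    dispatch_planning_queue(S, t)
    # the rest of the doctor's block is free again for queued tasks
    dispatch_contouring_queue(S, t)
  })

  set_handler(eng, "plan_done", function(eng, payload, t) {
    pid <- payload
    P$plan_done[pid] <- t
    S$busy[P$planner[pid]] <- S$busy[P$planner[pid]] - 1L
    if (eng$trace) {
      eng$log_res[eng$log_n] <- sprintf("planner_%d", P$planner[pid])
    }
    dispatch_planning_queue(S, t)
  })

  set_handler(eng, "checkpoint", function(eng, payload, t) {
    day <- payload
    if (!length(S$pending)) return(invisible())
    for (pid in S$pending) {
      # the day-ahead check does not apply to acute patients (their whole
      # pathway fits inside the start day; the start-instant check governs),
      # and at most one postponement decision is taken per day
      if (P$strategy[pid] == "pull" &&
          !is.na(P$sched_start_day[pid]) &&
          P$sched_start_day[pid] == day + 1L && is.na(P$plan_done[pid]) &&
          P$urgency[pid] != "acute" && P$last_rebook_day[pid] < day) {
        rebook_patient(S, pid)
      }
    }
  })

  set_handler(eng, "treat_start", function(eng, payload, t) {
    pid <- payload
    if (!is.na(P$plan_done[pid]) && P$plan_done[pid] <= t) {
      P$actual_start_day[pid] <- sim_day(t)
      P$start_ev[pid] <- NA_integer_
      S$pending <- S$pending[S$pending != pid]
    } else if (P$strategy[pid] == "pull") {
      rebook_patient(S, pid)
    } else {
      # push start slides forward without counting as a rebook
      set_start(S, pid, next_admissible_day(P$sched_start_day[pid],
                                            P$start_weekday[pid],
                                            S$holidays))
    }
  })
}

set_start <- function(S, pid, day) {
  P <- S$P
  if (!is.na(P$start_ev[pid]) && event_pending(S$eng, P$start_ev[pid])) {
    cancel_event(S$eng, P$start_ev[pid])
  } else if (is.na(P$start_ev[pid])) {
    S$pending <- c(S$pending, pid)
  }
  P$sched_start_day[pid] <- day
  # an acute 0-day start set after the nominal start instant is checked at once
  tt <- max(sim_time(day) + S$cfg$policies$rebook$start_tod, S$eng$clock)
  P$start_ev[pid] <- schedule_event(S$eng, tt, "treat_start", pid,
                                    priority = 9L)
}

rebook_patient <- function(S, pid) {
  P <- S$P
  P$rebooks[pid] <- P$rebooks[pid] + 1L
  P$last_rebook_day[pid] <- sim_day(S$eng$clock)
  new_day <- next_admissible_day(P$sched_start_day[pid],
                                 P$start_weekday[pid], S$holidays)
  set_start(S, pid, new_day)
  P$due_day[pid] <- new_day
}

# EDD dispatch of pending contouring tasks onto doctor free intervals.
# Non-palliative tasks go to the patient's assigned doctor only; palliative
# tasks (acute or bone metastasis) to any doctor. A task needs one
# contiguous free interval covering contouring plus peer review.
dispatch_contouring_queue <- function(S, now) {
  if (!length(S$contour_q) || is.null(S$iv_doc)) return(invisible())
  P <- S$P
  q <- S$contour_q[order(P$due_day[S$contour_q], S$contour_q)]
  served <- integer(0)
  for (pid in q) {
    dur <- P$cdur[pid]
    idx <- if (P$palliative[pid]) seq_along(S$iv_doc) else
      which(S$iv_doc == P$doctor[pid])
    if (!length(idx)) next
    # a task starts only at the current instant, inside an open block with
    # enough contiguous time left; future blocks are handled when they open
    ok <- S$iv_start[idx] <= now & now + dur <= S$iv_end[idx]
    if (!any(ok)) next
    row <- idx[which(ok)[1]]
    S$iv_start[row] <- now + dur
    P$contour_start[pid] <- now
    P$contour_doc[pid] <- S$iv_doc[row]
    schedule_event(S$eng, now + dur, "contour_done", pid, priority = 2L)
    served <- c(served, pid)
  }
  if (length(served)) S$contour_q <- setdiff(S$contour_q, served)
  invisible()
}

# EDD dispatch of planning tasks onto skill-matched planners with
# concurrency tokens; plans longer than the remaining workday resume the
# next working morning (software-driven tasks).
dispatch_planning_queue <- function(S, now) {
  if (!length(S$plan_q)) return(invisible())
  tod <- sim_tod(now)
  if (tod < S$pshift[1] || tod >= S$pshift[2] ||
      !is_workday(sim_day(now), S$holidays)) {
    return(invisible())
  }
  P <- S$P
  roster <- S$planners
  q <- S$plan_q[order(P$due_day[S$plan_q], S$plan_q)]
  served <- integer(0)
  for (pid in q) {
    ty <- P$planning_type[pid]
    base <- if (ty == "P4" && P$site[pid] %in% S$p3_extra) S$elig$P4x else
      S$elig[[ty]]
    elig <- base[S$busy[base] < S$pcap[base]]
    if (!length(elig)) next
    pl <- elig[order(S$busy[elig], elig)][1]
    S$busy[pl] <- S$busy[pl] + 1L
    dur <- P$pdur[pid]
    P$plan_start[pid] <- now
    P$planner[pid] <- pl
    done <- add_working_minutes(now, dur, S$pshift[1], S$pshift[2],
                                S$holidays)
    schedule_event(S$eng, done, "plan_done", pid, priority = 2L)
    if (P$strategy[pid] == "push" && is.na(P$sched_start_day[pid])) {
      sd <- schedule_start_push(sim_day(now), P$start_weekday[pid], S$cfg,
                                S$streams$ttt, holidays = S$holidays)
      set_start(S, pid, sd)
      P$due_day[pid] <- sd
    }
    served <- c(served, pid)
  }
  if (length(served)) S$plan_q <- setdiff(S$plan_q, served)
  invisible()
}

#' Audit stage precedence on a simulation result
#'
#' Checks, for every completed patient, the hard precedence
#' arrival <= CT <= last scan <= post-processing <= contouring <= planning
#' <= start of treatment, and that waiting times are non-negative.
#'
#' @param sim an `rt_sim`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
audit_precedence <- function(sim) {
  p <- sim$patients
  done <- !is.na(p$actual_start_day)
  chk <- function(ok, what) {
    if (!all(ok, na.rm = TRUE)) {
      stop(sprintf("precedence violated: %s (%d patient(s))", what,
                   sum(!ok, na.rm = TRUE)))
    }
  }
  chk(p$arrival <= p$ct_end, "arrival <= CT")
  chk(p$ct_end <= p$last_scan, "CT <= last scan")
  chk(p$last_scan <= p$ipp_done, "last scan <= post-processing")
  chk(p$ipp_done <= p$contour_start, "post-processing <= contouring start")
  chk(p$contour_start + 89 <= p$contour_done,
      "contouring occupies its full duration")
  chk(p$contour_done <= p$plan_start, "contouring <= planning start")
  chk(p$plan_start < p$plan_done, "planning start < planning done")
  chk(p$plan_done[done] <= sim_time(p$actual_start_day[done] + 1L),
      "plan finished by start of treatment day end")
  chk(p$actual_start_day[done] >= p$arrival_day[done],
      "start after arrival")
  invisible(TRUE)
}
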