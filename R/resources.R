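SLOT_LABELS <- c(unrestricted = 0L, no_iv_contrast_excluded = 1L,
                 acute_reserved = 2L)

#' Build a dated slot calendar for an imaging machine pool
#'
#' Generates booked/unbooked appointment slots for every working day up to
#' `n_days`. CT slots carry pre-allocation labels: the first two morning
#' slots of each scanner cannot take IV-contrast patients (the supervising
#' doctor's shift starts later), and one slot per day is reserved
#' exclusively for acute patients. MRI and PET-CT slots are unrestricted.
#'
#' @param config an `rt_config`.
#' @param kind `"ct"`, `"mri"` or `"petct"`.
#' @param n_days number of days to materialise.
#' @return a slot-calendar object for [find_earliest_slot()].
#' @export
build_slot_calendar <- function(config, kind = c("ct", "mri", "petct"),
                                n_days) {
  kind <- match.arg(kind)
  rc <- config$resources[[kind]]
  holidays <- as_sim_day(config$holidays, config$origin)
  days <- which(is_workday(0:(n_days - 1), holidays)) - 1L
  start <- integer(0); scanner <- integer(0); label <- integer(0)
  for (d in days) {
    if (kind == "ct") {
      for (s in seq_len(rc$n_machines)) {
        k <- seq_len(rc$slots_per_day) - 1L
        st <- sim_time(d) + rc$first_slot_tod + k * rc$slot_spacing
        lb <- rep(SLOT_LABELS[["unrestricted"]], rc$slots_per_day)
        lb[seq_len(rc$n_no_iv_slots)] <- SLOT_LABELS[["no_iv_contrast_excluded"]]
        if (s == 1L && rc$acute_reserved_per_day > 0L) {
          lb[rc$n_no_iv_slots + seq_len(rc$acute_reserved_per_day)] <-
            SLOT_LABELS[["acute_reserved"]]
        }
        start <- c(start, st); scanner <- c(scanner, rep(s, length(st)))
        label <- c(label, lb)
      }
    } else {
      nslots <- rc$weekly_slots[day_weekday(d)]
      if (nslots > 0L) {
        k <- seq_len(nslots) - 1L
        st <- sim_time(d) + rc$first_slot_tod + k * rc$slot_spacing
        start <- c(start, st); scanner <- c(scanner, rep(1L, length(st)))
        label <- c(label, rep(SLOT_LABELS[["unrestricted"]], length(st)))
      }
    }
  }
  o <- order(start, scanner)
  cal <- new.env(parent = emptyenv())
  cal$kind <- kind
  cal$start <- start[o]
  cal$end <- cal$start + rc$slot_minutes
  cal$scanner <- scanner[o]
  cal$label <- label[o]
  cal$booked <- logical(length(o))
  cal$ptr <- 1L
  class(cal) <- "slot_calendar"
  cal
}

#' @export
print.slot_calendar <- function(x, ...) {
  cat(sprintf("<slot_calendar> %s: %d slots, %d booked\n", x$kind,
              length(x$start), sum(x$booked)))
  invisible(x)
}

#' Find (and optionally book) the earliest admissible slot
#'
#' Appointments are assigned on a first-come-first-planned basis: the
#' chronologically first unbooked slot at or after `earliest` whose label
#' admits the patient. IV-contrast patients are excluded from the first two
#' morning CT slots; acute-reserved slots only admit acute patients.
#'
#' @param cal a slot calendar.
#' @param earliest earliest admissible time (minutes since origin).
#' @param acute is the patient acute?
#' @param iv_contrast does the patient need IV contrast before the scan?
#' @param book if `TRUE`, mark the returned slot booked.
#' @param horizon_days error if no slot exists within this many days of
#'   `earliest` (signals a capacity misconfiguration).
#' @return a list with `index`, `start`, `end`, `scanner`, or `NULL` when
#'   the calendar itself ends before `earliest + horizon_days`.
#' @export
find_earliest_slot <- function(cal, earliest, acute = FALSE,
                               iv_contrast = FALSE, book = TRUE,
                               horizon_days = 120L) {
  while (cal$ptr <= length(cal$start) && cal$booked[cal$ptr]) {
    cal$ptr <- cal$ptr + 1L
  }
  n <- length(cal$start)
  # slots are start-sorted: jump to the first slot at/after `earliest`
  i <- max(cal$ptr, findInterval(earliest - 1L, cal$start) + 1L)
  limit <- earliest + horizon_days * MIN_PER_DAY
  while (i <= n) {
    if (!cal$booked[i] && cal$start[i] >= earliest) {
      lb <- cal$label[i]
      ok <- lb == 0L || (lb == 1L && !iv_contrast) || (lb == 2L && acute)
      if (ok) {
        if (cal$start[i] > limit) {
          stop(sprintf("capacity misconfiguration: no admissible %s slot within %d days",
                       cal$kind, horizon_days))
        }
        if (book) cal$booked[i] <- TRUE
        return(list(index = i, start = cal$start[i], end = cal$end[i],
                    scanner = cal$scanner[i]))
      }
    }
    i <- i + 1L
  }
  if (n > 0L && cal$start[n] >= limit) {
    stop(sprintf("capacity misconfiguration: no admissible %s slot within %d days",
                 cal$kind, horizon_days))
  }
  NULL
}

#' Build synthetic staff agendas
#'
#' Creates one agenda per doctor from the team roster. Each doctor works the
#' configured shift on weekdays; scheduled duties (consultations, meetings,
#' administration) fill the rest, leaving a configured fraction of the shift
#' available for contouring. Under the default `"clustered"` template that
#' availability is concentrated on two weekly contouring days, as specialty
#' agendas typically are; the `"balanced"` template spreads the same weekly
#' minutes evenly over the five weekdays (at least two hours every day).
#' Random absence days (leave, conferences, illness) are drawn at the
#' configured annual rate.
#'
#' @param config an `rt_config`.
#' @param n_days number of simulated days to cover.
#' @param rng an agenda stream from [rng_streams()]; `NULL` for no absences.
#' @return list of agenda objects (id, team, template data, absent days).
#' @export
build_agendas <- function(config, n_days, rng = NULL) {
  dc <- config$resources$doctors
  holidays <- as_sim_day(config$holidays, config$origin)
  teams <- rep(names(dc$teams), dc$teams)
  shift_len <- dc$shift[2] - dc$shift[1]
  weekly_free <- round(dc$contour_fraction * shift_len) * 5L
  workdays <- which(is_workday(0:(n_days - 1), holidays)) - 1L
  p_abs <- dc$absence_days_per_year / 260
  agendas <- vector("list", length(teams))
  for (i in seq_along(teams)) {
    absent <- integer(0)
    if (!is.null(rng)) {
      absent <- with_rng(rng,
        workdays[stats::runif(length(workdays)) < p_abs])
    }
    contour_days <- sort(unique(c((i - 1L) %% 5L + 1L, (i + 1L) %% 5L + 1L)))
    if (length(contour_days) == 1L) {
      contour_days <- c(contour_days, contour_days %% 5L + 1L)
    }
    agendas[[i]] <- structure(list(
      id = i, team = teams[i], shift = dc$shift,
      template = dc$agenda, contour_days = contour_days,
      weekly_free = weekly_free, absent_days = absent,
      holidays = holidays), class = "staff_agenda")
  }
  agendas
}

#' Free (contouring-available) intervals of a doctor on a day
#'
#' The complement of the doctor's scheduled duties within the shift, minus
#' absences; empty on weekends, holidays and absence days.
#'
#' @param agenda a `staff_agenda` from [build_agendas()].
#' @param day simulation day index.
#' @return a 2-column matrix of `(start, end)` minutes since origin; zero
#'   rows when the doctor has no contouring time.
#' @export
doctor_free_intervals <- function(agenda, day) {
  none <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  if (!is_workday(day, agenda$holidays) || day %in% agenda$absent_days) {
    return(none)
  }
  base <- sim_time(day)
  s <- agenda$shift[1]
  wd <- day_weekday(day)
  if (identical(agenda$template, "balanced")) {
    daily <- agenda$weekly_free %/% 5L
    if (wd == 1L) daily <- daily + agenda$weekly_free %% 5L
    return(cbind(start = base + 600L, end = base + 600L + daily))
  }
  # clustered: ~70% of the weekly contouring time sits on two heavy days;
  # the other weekdays keep a short block (urgent contours fit, long
  # regular ones usually do not)
  heavy_each <- (agenda$weekly_free * 7L) %/% 20L
  light_each <- (agenda$weekly_free - 2L * heavy_each) %/% 3L
  rem <- agenda$weekly_free - 2L * heavy_each - 3L * light_each
  if (wd %in% agenda$contour_days) {
    alloc <- heavy_each + if (wd == agenda$contour_days[1]) rem else 0L
    morning <- min(280L, alloc)
    rest <- alloc - morning
    iv <- cbind(start = base + s, end = base + s + morning)
    if (rest > 0L) {
      iv <- rbind(iv, cbind(start = base + s + 320L,
                            end = base + s + 320L + rest))
    }
    return(iv)
  }
  cbind(start = base + 600L, end = base + 600L + light_each)
}

#' Build the planner roster
#'
#' Planning RTTs hold a skill level P2, P3 or P4; skills are downward
#' compatible (P4 covers P3 and P2; P3 covers P2) and P3/P4-level planners
#' can run two plans simultaneously, P2-level planners one.
#'
#' @param config an `rt_config`.
#' @return data.frame with columns `id`, `skill`, `capacity`.
#' @export
build_planner_roster <- function(config) {
  pc <- config$resources$planners
  skills <- rep(names(pc$counts), pc$counts)
  data.frame(id = seq_along(skills), skill = skills,
             capacity = unname(pc$concurrency[skills]),
             stringsAsFactors = FALSE)
}

#' Does a planner skill level cover a planning task?
#'
#' @param skill planner skill, `"P2"`, `"P3"` or `"P4"`.
#' @param plan_type planning type of the task.
#' @param site the patient's tumor site (used by the skill-upgrade
#'   scenario).
#' @param p3_extra_sites sites whose conventional (P4) plans P3-level
#'   planners may also process.
#' @return logical.
#' @export
skill_covers <- function(skill, plan_type, site = NA_character_,
                         p3_extra_sites = character()) {
  if (skill == "P4") return(TRUE)
  if (skill == "P3") {
    return(plan_type %in% c("P2", "P3") ||
             (plan_type == "P4" && !is.na(site) && site %in% p3_extra_sites))
  }
  plan_type == "P2"
}

#' Planners currently able to take a task
#'
#' @param plan_type planning type `"P2"`, `"P3"` or `"P4"`.
#' @param roster planner roster from [build_planner_roster()].
#' @param busy integer vector of concurrent plans per planner.
#' @param site tumor site of the task.
#' @param p3_extra_sites see [skill_covers()].
#' @param on_shift logical vector (default all on shift).
#' @return integer planner ids, possibly empty.
#' @export
eligible_planners <- function(plan_type, roster, busy = NULL,
                              site = NA_character_,
                              p3_extra_sites = character(),
                              on_shift = NULL) {
  if (is.null(busy)) busy <- integer(nrow(roster))
  if (is.null(on_shift)) on_shift <- rep(TRUE, nrow(roster))
  covers <- vapply(roster$skill, skill_covers, NA, plan_type = plan_type,
                   site = site, p3_extra_sites = p3_extra_sites,
                   USE.NAMES = FALSE)
  roster$id[covers & on_shift & busy < roster$capacity]
}
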