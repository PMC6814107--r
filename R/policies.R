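#' Pull/push strategy assignment
#'
#' Under the baseline workflow-control policy, acute patients, subacute
#' patients and regular patients whose radiotherapy is combined with another
#' treatment modality are scheduled in a pull fashion (first-fraction date
#' fixed right after consultation); all other regular patients are push
#' (date set only once treatment planning starts). The workflow-control
#' analysis promotes whole tumor sites to pull on top of the baseline.
#'
#' @param urgency character vector (`"acute"`, `"subacute"`, `"regular"`).
#' @param site tumor sites.
#' @param combined logical, combined-modality treatment.
#' @param promoted_sites tumor sites promoted to pull beyond the baseline.
#' @return character vector, `"pull"` or `"push"`.
#' @export
pull_policy <- function(urgency, site, combined,
                        promoted_sites = character()) {
  unknown <- setdiff(promoted_sites, TUMOR_SITES)
  if (length(unknown)) {
    stop(sprintf("unknown tumor site(s) in pull policy: %s",
                 paste(unknown, collapse = ", ")))
  }
  ifelse(urgency %in% c("acute", "subacute") | combined |
           site %in% promoted_sites, "pull", "push")
}

#' Next admissible treatment-start day
#'
#' The first workday strictly after `day` that satisfies the care plan's
#' start-weekday constraint (for example head-and-neck treatments start on
#' Mondays).
#'
#' @param day simulation day index.
#' @param start_weekday required weekday (1 = Monday) or `NA`.
#' @param holidays holiday day indices.
#' @export
next_admissible_day <- function(day, start_weekday = NA_integer_,
                                holidays = integer()) {
  d <- day + 1L
  repeat {
    if (is_workday(d, holidays) &&
        (is.na(start_weekday) || day_weekday(d) == start_weekday)) {
      return(d)
    }
    d <- d + 1L
  }
}

admissible_offsets <- function(base_day, support, start_weekday, holidays) {
  days <- base_day + support
  ok <- is_workday(days, holidays)
  if (!is.na(start_weekday)) ok <- ok & day_weekday(days) == start_weekday
  support[ok]
}

#' Draw a time-to-treatment for a pull patient
#'
#' Time-to-treatment (days from request to first fraction) is drawn from a
#' per-urgency discrete table whose support follows the published bounds —
#' 0-1 days for acute patients, 1-8 for subacute (and bone-metastasis)
#' patients, 3-21 for regular pull patients. The draw is conditioned on the
#' request weekday: only offsets landing on an admissible start day (a
#' workday satisfying the plan's start-weekday constraint) carry mass, which
#' is how a regular head-and-neck consultation on a Tuesday ends up with a
#' time to treatment of mostly 6 or 13 days.
#'
#' @param config an `rt_config`.
#' @param urgency urgency class.
#' @param base_day day the countdown starts from (request day plus any
#'   planned delay).
#' @param start_weekday required start weekday or `NA`.
#' @param rng a ttt stream.
#' @param holidays pre-computed holiday day indices (else derived from the
#'   config).
#' @return integer day offset from `base_day`.
#' @export
draw_ttt <- function(config, urgency, base_day, start_weekday = NA_integer_,
                     rng, holidays = NULL) {
  tt <- config$policies$ttt[[urgency]]
  if (is.null(tt)) stop(sprintf("config error: no time-to-treatment table for '%s'",
                                urgency))
  if (is.null(holidays)) holidays <- as_sim_day(config$holidays, config$origin)
  keep <- admissible_offsets(base_day, tt$support, start_weekday, holidays)
  if (!length(keep)) {
    # constraint unsatisfiable inside the support: first admissible day after
    d <- next_admissible_day(base_day + max(tt$support), start_weekday,
                             holidays)
    return(d - base_day)
  }
  w <- tt$weights[match(keep, tt$support)]
  if (length(keep) == 1L) return(keep)
  with_rng(rng, keep[sample.int(length(keep), 1L, prob = w)])
}

#' Set a pull patient's first-fraction date at consultation
#'
#' @param arrival_day consultation (request) day.
#' @param urgency urgency class.
#' @param delay_weeks planned pre-treatment delay in weeks (shifts the
#'   countdown, not the arrival).
#' @param start_weekday required start weekday or `NA`.
#' @param config an `rt_config`.
#' @param rng a ttt stream.
#' @return scheduled start day (simulation day index).
#' @export
schedule_start_pull <- function(arrival_day, urgency, delay_weeks = 0L,
                                start_weekday = NA_integer_, config, rng,
                                holidays = NULL) {
  base <- arrival_day + 7L * delay_weeks
  base + draw_ttt(config, urgency, base, start_weekday, rng, holidays)
}

#' Set a push patient's first-fraction date at treatment-planning start
#'
#' Push patients get a start date only once contouring is done and planning
#' has started; the gap between planning start and first fraction is drawn
#' from the configured 1-7 day table, conditioned on landing on an
#' admissible day.
#'
#' @param planning_start_day day treatment planning starts.
#' @inheritParams schedule_start_pull
#' @return scheduled start day.
#' @export
schedule_start_push <- function(planning_start_day,
                                start_weekday = NA_integer_, config, rng,
                                holidays = NULL) {
  tt <- config$policies$ttt$push_gap
  if (is.null(holidays)) holidays <- as_sim_day(config$holidays, config$origin)
  keep <- admissible_offsets(planning_start_day, tt$support, start_weekday,
                             holidays)
  if (!length(keep)) {
    d <- next_admissible_day(planning_start_day + max(tt$support),
                             start_weekday, holidays)
    return(d)
  }
  w <- tt$weights[match(keep, tt$support)]
  off <- if (length(keep) == 1L) keep else
    with_rng(rng, keep[sample.int(length(keep), 1L, prob = w)])
  planning_start_day + off
}

#' Book the imaging appointments for a patient
#'
#' Books the CT (always required) into the first admissible slot at or
#' after arrival plus any planned delay, then the MRI and PET-CT (when
#' flagged) into the first slots at or after the preceding scan, following
#' the pathway order CT, MRI, PET-CT.
#'
#' @param patient list/row with fields `arrival_day` (or `arrival` time),
#'   `delay_weeks`, `urgency`, `iv_contrast`, `mri`, `petct`.
#' @param cals named list of slot calendars (`ct`, `mri`, `petct`).
#' @param clock current time (minutes); bookings cannot precede it.
#' @param horizon_days booking horizon passed to [find_earliest_slot()].
#' @return list of booked slots (`ct`, and `mri`/`petct` when needed) plus
#'   `last_scan_end`.
#' @export
book_imaging <- function(patient, cals, clock = 0L, horizon_days = 120L) {
  earliest <- max(clock, sim_time(patient$arrival_day +
                                    7L * patient$delay_weeks))
  acute <- identical(patient$urgency, "acute")
  ct <- find_earliest_slot(cals$ct, earliest, acute = acute,
                           iv_contrast = isTRUE(patient$iv_contrast),
                           horizon_days = horizon_days)
  if (is.null(ct)) stop("capacity misconfiguration: CT calendar exhausted")
  res <- list(ct = ct)
  last_end <- ct$end
  if (isTRUE(patient$mri)) {
    mri <- find_earliest_slot(cals$mri, last_end, acute = acute,
                              horizon_days = horizon_days)
    if (is.null(mri)) stop("capacity misconfiguration: MRI calendar exhausted")
    res$mri <- mri
    last_end <- max(last_end, mri$end)
  }
  if (isTRUE(patient$petct)) {
    pet <- find_earliest_slot(cals$petct, last_end, acute = acute,
                              horizon_days = horizon_days)
    if (is.null(pet)) stop("capacity misconfiguration: PET-CT calendar exhausted")
    res$petct <- pet
    last_end <- max(last_end, pet$end)
  }
  res$last_scan_end <- last_end
  res
}

#' Lognormal image post-processing delays
#'
#' Warping (4DCT motion compensation) and image registration are modeled as
#' elapsed lognormal lags, moment-matched to the published mean and SD in
#' days: for target mean m and standard deviation s the underlying normal
#' parameters are `sigma^2 = log(1 + (s/m)^2)` and
#' `mu = log(m) - sigma^2/2`.
#'
#' @param n number of draws.
#' @param mean,sd target moments in days.
#' @param rng an ipp stream.
#' @return delays in days (non-negative).
#' @export
draw_ipp_delay <- function(n, mean, sd, rng) {
  if (mean <= 0) stop("config error: lognormal delay mean must be positive")
  s2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - s2 / 2
  with_rng(rng, stats::rlnorm(n, meanlog = mu, sdlog = sqrt(s2)))
}

#' Image post-processing completion time
#'
#' Ready-for-contouring time: the last scan end plus the warping lag (when
#' flagged) plus the image-registration lag (when flagged). The lags are
#' pure elapsed time and consume no staff capacity.
#'
#' @param last_scan_end minutes since origin.
#' @param warping,image_registration logical step flags.
#' @param config an `rt_config`.
#' @param rng an ipp stream.
#' @return ready time in minutes since origin.
#' @export
apply_ipp_delays <- function(last_scan_end, warping, image_registration,
                             config, rng) {
  ipp <- config$service_times$ipp
  t <- last_scan_end
  if (isTRUE(warping)) {
    t <- t + round(draw_ipp_delay(1, ipp$warping[["mean"]],
                                  ipp$warping[["sd"]], rng) * MIN_PER_DAY)
  }
  if (isTRUE(image_registration)) {
    t <- t + round(draw_ipp_delay(1, ipp$image_registration[["mean"]],
                                  ipp$image_registration[["sd"]], rng) *
                     MIN_PER_DAY)
  }
  as.integer(t)
}
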