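#' Sample one day's patient arrivals
#'
#' Arrivals on each workday are independent Poisson counts per tumor site;
#' the daily total is therefore Poisson with the summed rate. There are no
#' weekend arrivals.
#'
#' @param weekday weekday index 1 (Monday) to 5 (Friday).
#' @param site_rates named non-negative rates (patients/day) per tumor site.
#' @param rng an arrivals stream from [rng_streams()].
#' @return named integer vector of counts per site.
#' @export
sample_daily_arrivals <- function(weekday, site_rates, rng) {
  if (!(weekday %in% 1:5)) stop("weekday must be 1 (Mon) .. 5 (Fri)")
  if (any(site_rates < 0)) stop("config error: negative arrival rate")
  counts <- with_rng(rng, stats::rpois(length(site_rates), site_rates))
  stats::setNames(as.integer(counts), names(site_rates))
}

#' Split weekday arrival totals across tumor sites
#'
#' Thinning a Poisson process with fixed proportions preserves Poisson
#' marginals, so per-site generators with these rates reproduce the weekday
#' totals in distribution.
#'
#' @param weekday_totals named numeric vector of per-weekday mean totals.
#' @param site_proportions proportions per site, summing to 1.
#' @return matrix of rates, sites in rows and weekdays in columns.
#' @export
split_rates_by_site <- function(weekday_totals, site_proportions) {
  if (abs(sum(site_proportions) - 1) > 1e-9) {
    stop("config error: site proportions must sum to 1")
  }
  outer(site_proportions, weekday_totals)
}

#' Draw full care content for a batch of patients
#'
#' Given tumor sites, assigns each patient a care plan from the catalogue
#' and draws urgency, imaging/post-processing steps, planning type, planned
#' delay, IV-contrast need, combined-modality status, specialty team and the
#' pull/push strategy label. All patients implicitly require a CT,
#' contouring and treatment planning.
#'
#' @param config an `rt_config`.
#' @param sites character vector of tumor sites, one per patient.
#' @param rng a care-content stream.
#' @return a data.frame with one row per patient.
#' @export
draw_care_content <- function(config, sites, rng) {
  n <- length(sites)
  plans <- config$care_plans
  promoted <- config$policies$pull_sites_promoted
  out <- data.frame(
    site = sites, plan = NA_character_, urgency = NA_character_,
    mri = FALSE, petct = FALSE, warping = FALSE,
    image_registration = FALSE, beam_setup = FALSE,
    planning_type = NA_character_, delay_weeks = 0L, combined = FALSE,
    iv_contrast = FALSE, team = NA_character_, palliative = FALSE,
    start_weekday = NA_integer_, strategy = NA_character_,
    stringsAsFactors = FALSE
  )
  with_rng(rng, {
    for (site in unique(sites)) {
      idx <- which(sites == site)
      site_plans <- Filter(function(pl) pl$tumor_site == site, plans)
      if (!length(site_plans)) {
        stop(sprintf("config error: no care plan for tumor site '%s'", site))
      }
      psel <- vapply(site_plans, `[[`, 0, "p_select")
      pick <- sample.int(length(site_plans), length(idx), replace = TRUE,
                         prob = psel)
      for (k in seq_along(site_plans)) {
        pl <- site_plans[[k]]
        rows <- idx[pick == k]
        m <- length(rows)
        if (!m) next
        out$plan[rows] <- pl$id
        urg <- URGENCIES[sample.int(3, m, replace = TRUE, prob = pl$urgency)]
        out$urgency[rows] <- urg
        out$mri[rows] <- stats::runif(m) < pl$steps[["mri"]]
        out$petct[rows] <- stats::runif(m) < pl$steps[["petct"]]
        out$warping[rows] <- stats::runif(m) < pl$steps[["warping"]]
        out$image_registration[rows] <-
          stats::runif(m) < pl$steps[["image_registration"]]
        bs <- stats::runif(m) < pl$p_beam_setup
        out$beam_setup[rows] <- bs
        p3 <- stats::runif(m) < pl$p_p3_fallback
        out$planning_type[rows] <- ifelse(bs, "P2", ifelse(p3, "P3", "P4"))
        delayed <- stats::runif(m) < pl$p_planned_delay
        wk <- integer(m)
        if (any(delayed)) {
          wk[delayed] <- sample.int(8, sum(delayed), replace = TRUE,
                                    prob = pl$delay_weeks_probs)
        }
        out$delay_weeks[rows] <- wk
        out$combined[rows] <- urg == "regular" &
          stats::runif(m) < pl$p_combined_regular
        out$iv_contrast[rows] <- stats::runif(m) < pl$p_iv_contrast
        out$team[rows] <- names(pl$teams)[
          sample.int(length(pl$teams), m, replace = TRUE, prob = pl$teams)]
        out$start_weekday[rows] <- pl$start_weekday
      }
    }
  })
  out$palliative <- out$urgency == "acute" | out$site == "bone_metastasis"
  out$strategy <- pull_policy(out$urgency, out$site, out$combined, promoted)
  out
}

#' Complete a single patient's care content
#'
#' Single-patient wrapper around [draw_care_content()], matching the flow of
#' the simulator where each arriving patient is completed in turn.
#'
#' @param patient a list with at least `tumor_site`.
#' @param config an `rt_config`.
#' @param rng a care-content stream.
#' @return the patient list with care-content fields filled in.
#' @export
assign_care_content <- function(patient, config, rng) {
  row <- draw_care_content(config, patient$tumor_site, rng)
  c(patient, as.list(row[, setdiff(names(row), "site")]))
}

#' Sample a planned pre-treatment delay
#'
#' A fraction of patients have their pre-treatment start intentionally
#' delayed for medical or personal reasons; the delay shifts the earliest CT
#' date, not the arrival time, and ranges between 1 and 8 weeks.
#'
#' @param plan a care-plan entry of the catalogue.
#' @param rng a care-content stream.
#' @param n number of draws.
#' @return integer weeks in `{0, 1..8}`.
#' @export
sample_planned_delay <- function(plan, rng, n = 1L) {
  with_rng(rng, {
    delayed <- stats::runif(n) < plan$p_planned_delay
    wk <- integer(n)
    if (any(delayed)) {
      wk[delayed] <- sample.int(8, sum(delayed), replace = TRUE,
                                prob = plan$delay_weeks_probs)
    }
    wk
  })
}

#' Sample a synthetic patient population
#'
#' Draws tumor sites from the stationary site mix implied by the arrival
#' rate matrix, then assigns full care content. This is the population view
#' of the case-mix generator used for input-distribution checks; the
#' simulator itself generates the same content patient-by-patient as
#' arrivals occur.
#'
#' @param config an `rt_config`.
#' @param n number of patients.
#' @param seed integer seed (uses the care-content stream).
#' @return a data.frame, one row per patient.
#' @examples
#' pop <- sample_patients(default_config(), 1000, seed = 1)
#' mean(pop$urgency == "subacute")
#' @export
sample_patients <- function(config, n, seed = 1L) {
  streams <- rng_streams(seed, 1L)
  sh <- site_shares(config)
  sites <- with_rng(streams$arrivals,
                    names(sh)[sample.int(length(sh), n, replace = TRUE,
                                         prob = sh)])
  draw_care_content(config, sites, streams$care_content)
}
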