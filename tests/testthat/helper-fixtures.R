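# Fixtures for deterministic micro-scenarios: a one-site department with
# degenerate randomness so trajectories can be hand-traced.

# A config with a single tumor site routed to a one-doctor team, balanced
# daily agendas, no absences, no imaging extras, and point-mass policy
# tables. `tweak` overrides selected pieces after construction.
micro_config <- function(urgency = "regular",
                         combined = FALSE,
                         planning_type = c("P3", "P2", "P4"),
                         planning_minutes = 240L,
                         push_gap_day = 2L,
                         ttt_day = NULL,
                         start_weekday = NA_integer_) {
  planning_type <- match.arg(planning_type)
  cfg <- default_config()
  cfg$holidays <- character()
  site <- "breast"
  urg <- c(acute = 0, subacute = 0, regular = 0)
  urg[urgency] <- 1
  plan <- list(
    id = "micro", p_select = 1, urgency = urg,
    tumor_site = site,
    steps = c(mri = 0, petct = 0, warping = 0, image_registration = 0),
    p_beam_setup = if (planning_type == "P2") 1 else 0,
    beam_setup_mode = "instead",
    p_p3_fallback = if (planning_type == "P3") 1 else 0,
    p_combined_regular = as.numeric(combined),
    p_iv_contrast = 0,
    planning_minutes = c(P2 = planning_minutes, P3 = planning_minutes,
                         P4 = planning_minutes),
    teams = c(Breast = 1),
    start_weekday = start_weekday,
    p_planned_delay = 0,
    delay_weeks_probs = rep(1 / 8, 8)
  )
  other_plans <- Filter(function(pl) pl$tumor_site != site, cfg$care_plans)
  cfg$care_plans <- c(list(micro = plan), other_plans)
  # arrivals off by default; tests inject arrivals explicitly
  cfg$arrivals$rate_matrix[] <- 0
  cfg$arrivals$weekday_totals[] <- 0
  cfg$arrivals$consult_window <- c(480L, 481L)  # consults at 08:00 sharp
  cfg$resources$doctors$teams <- c(Lung = 1L, HeadNeck = 1L, Breast = 1L,
                                   CNS = 1L, Gynecology = 1L, GI = 1L,
                                   Urology = 1L)
  cfg$resources$doctors$agenda <- "balanced"
  cfg$resources$doctors$absence_days_per_year <- 0
  cfg$policies$ttt$push_gap <- list(support = push_gap_day, weights = 1)
  if (!is.null(ttt_day)) {
    cfg$policies$ttt[[urgency]] <- list(support = ttt_day, weights = 1)
  }
  cfg
}

# run a micro simulation with injected arrivals (days + site)
micro_sim <- function(cfg, days, n_days = 30L, seed = 1L) {
  simulate_rt(cfg, seed = seed, warmup_days = 0, horizon_days = n_days,
              arrivals_override = data.frame(day = days, site = "breast"))
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.5g - %.5g| <= %.3g", actual, expected, tol))
}
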