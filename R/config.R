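TUMOR_SITES <- c("bone_metastasis", "breast", "lung", "brain", "prostate",
                 "head_and_neck", "chest_wall", "others")

DOCTOR_TEAMS <- c(Lung = 7L, HeadNeck = 9L, Breast = 9L, CNS = 3L,
                  Gynecology = 4L, GI = 5L, Urology = 7L)

URGENCIES <- c("acute", "subacute", "regular")

# Scale per-site propensity weights so the population mixture hits `target`
# exactly: p_site = c * w_site with c chosen so sum(shares * p) == target.
scale_to_target <- function(w, shares, target) {
  p <- w * (target / sum(shares * w))
  if (any(p < 0 | p > 1)) {
    stop("calibration produced a probability outside [0, 1]; adjust weights")
  }
  p
}

#' Default department configuration
#'
#' Builds the bundled department configuration: weekday-dependent Poisson
#' arrival rates, a care-plan catalogue (two plans per tumor site — a
#' palliative/urgent plan and a standard regular plan), machine slot
#' templates, doctor and planner rosters, time-to-treatment tables, national
#' waiting-time targets and experiment settings.
#'
#' The per-care-plan empirical distributions of the source department are
#' not public, so the catalogue is calibrated instead: per-site step
#' propensity weights are rescaled so that the population mixture reproduces
#' every published marginal exactly — weekday arrival means (Mon 17.5, Tue
#' 20.9, Wed 23.2, Thu 21.7, Fri 15.5), urgency mix (acute 1.3%, subacute
#' 30.8%, regular 67.9%), step prevalences (MRI 18.5%, PET-CT 3.9%, warping
#' 12.4%, image registration 29.7%, beam set-up 34.7%), planned-delay
#' fraction (13%), baseline pull share (40.8%) and the bone-metastasis P2
#' share (93%). Per-site shares of the arrival process are approximate
#' (chosen realistic) because only the weekday totals are published.
#'
#' @param planner_preset `"stated_total"` keeps the published total of 24
#'   planning RTTs (3 at P2, 7 at P3, 14 at P4); `"enumerated"` uses the
#'   published 3/7/10 enumeration (total 20).
#' @return an `rt_config` object (a validated nested list).
#' @examples
#' cfg <- default_config()
#' config_marginals(cfg)
#' @export
default_config <- function(planner_preset = c("stated_total", "enumerated")) {
  planner_preset <- match.arg(planner_preset)

  weekday_totals <- c(Mon = 17.5, Tue = 20.9, Wed = 23.2, Thu = 21.7,
                      Fri = 15.5)
  shares <- c(bone_metastasis = 0.170, breast = 0.260, lung = 0.124,
              brain = 0.060, prostate = 0.110, head_and_neck = 0.070,
              chest_wall = 0.040, others = 0.166)
  week_total <- sum(weekday_totals)
  site_week <- shares * week_total

  # Weekday consultation patterns for six sites (rows sum to 1); breast and
  # "others" absorb the residual so column sums equal the weekday totals.
  # site-specific consultation clinics cluster heavily on fixed weekdays
  # (lung on Wednesdays, prostate on Tuesdays, ...); palliative referrals
  # arrive throughout the week
  pat <- rbind(
    bone_metastasis = c(0.22, 0.20, 0.20, 0.20, 0.18),
    lung            = c(0.08, 0.10, 0.60, 0.14, 0.08),
    brain           = c(0.10, 0.15, 0.10, 0.50, 0.15),
    prostate        = c(0.10, 0.55, 0.10, 0.15, 0.10),
    head_and_neck   = c(0.42, 0.08, 0.08, 0.35, 0.07),
    chest_wall      = c(0.20, 0.20, 0.20, 0.20, 0.20)
  )
  fixed <- pat * site_week[rownames(pat)]
  residual <- weekday_totals - colSums(fixed)
  stopifnot(all(residual > 0))
  resid_share <- site_week[c("breast", "others")] /
    sum(site_week[c("breast", "others")])
  rate_matrix <- rbind(fixed,
                       breast = residual * resid_share[["breast"]],
                       others = residual * resid_share[["others"]])
  rate_matrix <- rate_matrix[TUMOR_SITES, ]
  colnames(rate_matrix) <- names(weekday_totals)

  # --- care content calibration (site shares are exact row sums) ----------
  p_acute <- scale_to_target(
    c(bone_metastasis = 4, breast = 0.2, lung = 1, brain = 1.5,
      prostate = 0.2, head_and_neck = 0.2, chest_wall = 0.2, others = 1),
    shares, 0.013)
  p_sub <- scale_to_target(
    c(bone_metastasis = 2.8, breast = 0.45, lung = 1.2, brain = 1.3,
      prostate = 0.3, head_and_neck = 0.8, chest_wall = 0.8, others = 1.2),
    shares, 0.308)
  p_reg <- 1 - p_acute - p_sub

  p_mri <- scale_to_target(
    c(bone_metastasis = 0.2, breast = 0.3, lung = 1, brain = 3,
      prostate = 2, head_and_neck = 2, chest_wall = 0.3, others = 1),
    shares, 0.185)
  p_petct <- scale_to_target(
    c(bone_metastasis = 0.2, breast = 0.2, lung = 3, brain = 0.2,
      prostate = 0.2, head_and_neck = 2, chest_wall = 0.2, others = 1.5),
    shares, 0.039)
  p_warp <- scale_to_target(
    c(bone_metastasis = 0.1, breast = 0.3, lung = 4, brain = 0.1,
      prostate = 0.1, head_and_neck = 0.1, chest_wall = 3, others = 1),
    shares, 0.124)
  p_imreg <- scale_to_target(
    c(bone_metastasis = 0.2, breast = 0.4, lung = 1.2, brain = 1.8,
      prostate = 1.5, head_and_neck = 2, chest_wall = 0.4, others = 1),
    shares, 0.297)

  # beam set-up (P2): fixed at 93% for bone metastasis, never for
  # head-and-neck; other sites calibrated to the 34.7% population share.
  p_p2 <- c(bone_metastasis = 0.93, head_and_neck = 0)
  rest <- setdiff(TUMOR_SITES, names(p_p2))
  target_rest <- 0.347 - shares[["bone_metastasis"]] * 0.93
  w_p2 <- c(breast = 1, lung = 0.3, brain = 0.3, prostate = 0.3,
            chest_wall = 0.5, others = 0.8)
  p_p2_rest <- w_p2 * (target_rest / sum(shares[rest] * w_p2[rest]))
  p_p2 <- c(p_p2, p_p2_rest[rest])[TUMOR_SITES]
  stopifnot(all(p_p2 >= 0 & p_p2 <= 1))

  # combined-modality probability among regular patients, calibrated so the
  # baseline pull share (acute + subacute + combined regular) is 40.8%.
  w_comb <- c(bone_metastasis = 0.5, breast = 1.2, lung = 1.3, brain = 0.8,
              prostate = 0.3, head_and_neck = 1.5, chest_wall = 1,
              others = 1)
  target_comb <- 0.408 - 0.013 - 0.308
  p_comb <- w_comb * (target_comb / sum(shares * p_reg * w_comb))
  stopifnot(all(p_comb >= 0 & p_comb <= 1))

  # planned delay only makes clinical sense for regular patients; the
  # regular-plan probability reproduces the 13% population fraction.
  p_delay_std <- 0.13 / sum(shares * p_reg)

  p3_fallback <- c(bone_metastasis = 0, breast = 1, lung = 0, brain = 0,
                   prostate = 1, head_and_neck = 0, chest_wall = 0,
                   others = 0.35)
  p4_minutes <- c(bone_metastasis = 300, breast = 400, lung = 700,
                  brain = 600, prostate = 350, head_and_neck = 960,
                  chest_wall = 450, others = 500)
  p3_minutes <- c(bone_metastasis = 150, breast = 240, lung = 300,
                  brain = 300, prostate = 150, head_and_neck = 300,
                  chest_wall = 300, others = 300)
  p2_minutes <- c(bone_metastasis = 60, breast = 120, lung = 90, brain = 90,
                  prostate = 90, head_and_neck = 90, chest_wall = 90,
                  others = 90)
  p_iv <- c(bone_metastasis = 0.10, breast = 0.15, lung = 0.25,
            brain = 0.30, prostate = 0.15, head_and_neck = 0.30,
            chest_wall = 0.15, others = 0.20)
  teams_for <- list(
    bone_metastasis = c(GI = 1), breast = c(Breast = 1), lung = c(Lung = 1),
    brain = c(CNS = 1), prostate = c(Urology = 1),
    head_and_neck = c(HeadNeck = 1), chest_wall = c(Breast = 1),
    others = c(Gynecology = 0.5, GI = 0.5))

  care_plans <- list()
  pal_step_factor <- 0.35  # palliative trajectories carry fewer extra steps
  for (site in TUMOR_SITES) {
    pa <- p_acute[[site]]; ps <- p_sub[[site]]
    psel_pal <- pa + ps
    site_steps <- c(mri = p_mri[[site]], petct = p_petct[[site]],
                    warping = p_warp[[site]],
                    image_registration = p_imreg[[site]])
    pal_steps <- pal_step_factor * site_steps
    # standard-plan probabilities keep the site-level mixture exact
    std_steps <- site_steps * (1 - pal_step_factor * psel_pal) /
      (1 - psel_pal)
    stopifnot(all(std_steps <= 1))
    common <- list(
      tumor_site = site,
      p_beam_setup = p_p2[[site]],
      beam_setup_mode = "instead",
      p_p3_fallback = p3_fallback[[site]],
      p_combined_regular = p_comb[[site]],
      p_iv_contrast = p_iv[[site]],
      planning_minutes = c(P2 = p2_minutes[[site]], P3 = p3_minutes[[site]],
                           P4 = p4_minutes[[site]]),
      teams = teams_for[[site]],
      start_weekday = if (site == "head_and_neck") 1L else NA_integer_
    )
    pal <- c(list(id = paste0(site, "_palliative"),
                  p_select = psel_pal,
                  urgency = c(acute = pa / psel_pal,
                              subacute = ps / psel_pal, regular = 0),
                  steps = pal_steps,
                  p_planned_delay = 0,
                  delay_weeks_probs = rep(1 / 8, 8)), common)
    std <- c(list(id = paste0(site, "_standard"),
                  p_select = 1 - psel_pal,
                  urgency = c(acute = 0, subacute = 0, regular = 1),
                  steps = std_steps,
                  p_planned_delay = p_delay_std,
                  delay_weeks_probs = rep(1 / 8, 8)), common)
    care_plans[[pal$id]] <- pal
    care_plans[[std$id]] <- std
  }

  planners <- switch(planner_preset,
                     stated_total = c(P2 = 3L, P3 = 7L, P4 = 14L),
                     enumerated = c(P2 = 3L, P3 = 7L, P4 = 10L))

  ttt <- list(
    acute = list(support = 0:1, weights = c(0.6, 0.4)),
    subacute = list(support = 1:8, weights = 0.95^(0:7)),
    regular = list(support = 3:21, weights = 0.93^(0:18)),
    push_gap = list(support = 1:7, weights = 0.75^(0:6))
  )

  cfg <- list(
    origin = "2017-01-02",
    holidays = c("2017-01-02", "2017-04-14", "2017-04-17", "2017-05-25",
                 "2017-08-15", "2017-12-25", "2017-12-26", "2018-05-01"),
    arrivals = list(
      weekday_totals = weekday_totals,
      rate_matrix = rate_matrix,
      consult_window = c(480L, 1020L)   # consults spread 08:00-17:00
    ),
    care_plans = care_plans,
    resources = list(
      ct = list(n_machines = 2L, slots_per_day = 13L, slot_minutes = 25L,
                first_slot_tod = 450L, slot_spacing = 45L,
                n_no_iv_slots = 2L, acute_reserved_per_day = 1L,
                iv_restriction_scope = "per_scanner"),
      mri = list(n_machines = 1L, weekly_slots = c(8L, 7L, 8L, 7L, 7L),
                 slot_minutes = 45L, first_slot_tod = 480L,
                 slot_spacing = 60L),
      petct = list(n_machines = 1L, weekly_slots = c(1L, 1L, 1L, 1L, 1L),
                   slot_minutes = 45L, first_slot_tod = 600L,
                   slot_spacing = 60L),
      booking_horizon_days = 120L,
      doctors = list(teams = DOCTOR_TEAMS, shift = c(480L, 1020L),
                     contour_fraction = 0.35, agenda = "clustered",
                     absence_days_per_year = 25),
      planners = list(counts = planners, shift = c(480L, 1020L),
                      concurrency = c(P2 = 1L, P3 = 2L, P4 = 2L))
    ),
    service_times = list(
      ct = 25L, mri = 45L, petct = 45L,
      contour = c(acute = 30L, subacute = 30L, regular = 60L),
      peer_review = 60L,
      ipp = list(warping = c(mean = 0.4, sd = 0.6),
                 image_registration = c(mean = 0.1, sd = 1.0))
    ),
    policies = list(
      pull_sites_promoted = character(),
      ttt = ttt,
      rebook = list(checkpoint_tod = 1050L, start_tod = 960L,
                    rule = "next_admissible"),
      backward_scheduling = FALSE,
      p3_extra_sites = character()      # set by scenario S4
    ),
    targets = c(acute = 1L, subacute = 10L, regular = 28L),
    kpi = list(waiting_time_excludes_planned_delay = TRUE),
    experiment = list(replications = 15L, warmup_days = 130L,
                      horizon_days = 365L),
    sweep_order = c("bone_metastasis", "breast", "prostate", "chest_wall",
                    "brain", "lung", "others", "head_and_neck")
  )
  class(cfg) <- "rt_config"
  validate_config(cfg)
  cfg
}

#' Site shares implied by the arrival-rate matrix
#' @param config an `rt_config`.
#' @return named numeric vector over tumor sites summing to 1.
#' @export
site_shares <- function(config) {
  rs <- rowSums(config$arrivals$rate_matrix)
  rs / sum(rs)
}

#' Analytic population marginals implied by a configuration
#'
#' Computes, in closed form from the catalogue and the arrival-rate matrix,
#' the population fractions the case-mix sampler should converge to. Used as
#' the independent oracle against sampled frequencies.
#'
#' @param config an `rt_config`.
#' @return named numeric vector of fractions.
#' @export
config_marginals <- function(config) {
  sh <- site_shares(config)
  plans <- config$care_plans
  agg <- c(acute = 0, subacute = 0, regular = 0, mri = 0, petct = 0,
           warping = 0, image_registration = 0, beam_setup = 0, pull = 0,
           planned_delay = 0, p2 = 0, bone_p2 = 0)
  bone_mass <- 0
  for (pl in plans) {
    m <- sh[[pl$tumor_site]] * pl$p_select
    agg["acute"] <- agg["acute"] + m * pl$urgency[["acute"]]
    agg["subacute"] <- agg["subacute"] + m * pl$urgency[["subacute"]]
    agg["regular"] <- agg["regular"] + m * pl$urgency[["regular"]]
    for (st in names(pl$steps)) agg[st] <- agg[st] + m * pl$steps[[st]]
    agg["beam_setup"] <- agg["beam_setup"] + m * pl$p_beam_setup
    agg["p2"] <- agg["p2"] + m * pl$p_beam_setup
    pull_sites <- config$policies$pull_sites_promoted
    p_pull <- pl$urgency[["acute"]] + pl$urgency[["subacute"]] +
      pl$urgency[["regular"]] *
      (if (pl$tumor_site %in% pull_sites) 1 else pl$p_combined_regular)
    agg["pull"] <- agg["pull"] + m * p_pull
    agg["planned_delay"] <- agg["planned_delay"] + m * pl$p_planned_delay
    if (pl$tumor_site == "bone_metastasis") {
      bone_mass <- bone_mass + m
      agg["bone_p2"] <- agg["bone_p2"] + m * pl$p_beam_setup
    }
  }
  agg["bone_p2"] <- agg["bone_p2"] / bone_mass
  agg
}

#' Validate a configuration
#'
#' Checks the structural invariants the simulator relies on: probability
#' vectors sum to one, rates are non-negative, slot capacities and rosters
#' are positive, delay lengths are between 1 and 8 weeks, and targets
#' increase with decreasing urgency.
#'
#' @param config an `rt_config`.
#' @return the config, invisibly; errors describe the offending field.
#' @export
validate_config <- function(config) {
  a <- config$arrivals
  if (any(a$rate_matrix < 0)) stop("config error: negative arrival rate")
  if (!isTRUE(all.equal(colSums(a$rate_matrix),
                        unname(a$weekday_totals) * 1, tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("config error: rate matrix columns must sum to the weekday totals")
  }
  for (site in TUMOR_SITES) {
    psel <- sum(vapply(config$care_plans, function(pl)
      if (pl$tumor_site == site) pl$p_select else 0, 0))
    if (abs(psel - 1) > 1e-9) {
      stop(sprintf("config error: plan selection for %s sums to %.6f", site,
                   psel))
    }
  }
  for (pl in config$care_plans) {
    if (abs(sum(pl$urgency) - 1) > 1e-9) {
      stop(sprintf("config error: urgency mix of %s does not sum to 1",
                   pl$id))
    }
    if (abs(sum(pl$delay_weeks_probs) - 1) > 1e-9 ||
        length(pl$delay_weeks_probs) != 8) {
      stop(sprintf("config error: delay distribution of %s must cover 1-8 weeks",
                   pl$id))
    }
    probs <- c(pl$steps, pl$p_beam_setup, pl$p_p3_fallback,
               pl$p_combined_regular, pl$p_planned_delay, pl$p_iv_contrast)
    if (any(probs < 0 | probs > 1)) {
      stop(sprintf("config error: probability outside [0,1] in %s", pl$id))
    }
    if (abs(sum(pl$teams) - 1) > 1e-9) {
      stop(sprintf("config error: team weights of %s do not sum to 1", pl$id))
    }
  }
  for (u in names(config$policies$ttt)) {
    tt <- config$policies$ttt[[u]]
    if (length(tt$support) != length(tt$weights) || any(tt$weights < 0) ||
        sum(tt$weights) <= 0) {
      stop(sprintf("config error: invalid time-to-treatment table '%s'", u))
    }
  }
  tg <- config$targets
  if (!(tg[["acute"]] < tg[["subacute"]] && tg[["subacute"]] < tg[["regular"]])) {
    stop("config error: waiting-time targets must increase with urgency class")
  }
  if (any(unlist(config$resources$planners$counts) < 0) ||
      any(unlist(config$resources$doctors$teams) <= 0)) {
    stop("config error: rosters must be positive")
  }
  unknown <- setdiff(config$policies$pull_sites_promoted, TUMOR_SITES)
  if (length(unknown)) {
    stop(sprintf("config error: unknown tumor site(s) in pull policy: %s",
                 paste(unknown, collapse = ", ")))
  }
  invisible(config)
}

#' Read or write a configuration as YAML
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$arrivals$weekday_totals <- unlist(raw$arrivals$weekday_totals)
  rm_ <- do.call(rbind, raw$arrivals$rate_matrix)
  colnames(rm_) <- names(raw$arrivals$weekday_totals)
  raw$arrivals$rate_matrix <- rm_
  raw$arrivals$consult_window <- as.integer(unlist(raw$arrivals$consult_window))
  raw$care_plans <- lapply(raw$care_plans, function(pl) {
    for (f in c("urgency", "steps", "planning_minutes", "teams")) {
      pl[[f]] <- unlist(pl[[f]])
    }
    pl$delay_weeks_probs <- as.numeric(unlist(pl$delay_weeks_probs))
    pl$start_weekday <- if (is.null(pl$start_weekday)) NA_integer_ else
      as.integer(pl$start_weekday)
    pl
  })
  raw$targets <- unlist(raw$targets)
  raw$policies$ttt <- lapply(raw$policies$ttt, function(tt)
    list(support = as.integer(unlist(tt$support)),
         weights = as.numeric(unlist(tt$weights))))
  raw$policies$pull_sites_promoted <-
    as.character(unlist(raw$policies$pull_sites_promoted))
  raw$policies$p3_extra_sites <-
    as.character(unlist(raw$policies$p3_extra_sites))
  raw$resources$doctors$teams <-
    vapply(raw$resources$doctors$teams, as.integer, 0L)
  raw$resources$planners$counts <-
    vapply(raw$resources$planners$counts, as.integer, 0L)
  raw$resources$planners$concurrency <-
    vapply(raw$resources$planners$concurrency, as.integer, 0L)
  raw$service_times$contour <- vapply(raw$service_times$contour, as.integer, 0L)
  raw$service_times$ipp <- lapply(raw$service_times$ipp, unlist)
  class(raw) <- "rt_config"
  validate_config(raw)
  raw
}

#' @rdname read_config
#' @param config an `rt_config`.
#' @export
write_config <- function(config, path) {
  ser <- unclass(config)
  ser$arrivals$rate_matrix <- lapply(
    seq_len(nrow(config$arrivals$rate_matrix)),
    function(i) unname(config$arrivals$rate_matrix[i, ]))
  names(ser$arrivals$rate_matrix) <- rownames(config$arrivals$rate_matrix)
  # yaml drops names of atomic vectors; turn them into maps
  namify <- function(x) {
    if (is.list(x)) {
      lapply(x, namify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(namify(ser), path, precision = 15L)
  invisible(path)
}

#' @export
print.rt_config <- function(x, ...) {
  cat("<rt_config>\n")
  cat(sprintf("  arrivals: %.1f patients/week over %d tumor sites\n",
              sum(x$arrivals$weekday_totals), nrow(x$arrivals$rate_matrix)))
  cat(sprintf("  care plans: %d; doctors: %d; planning RTTs: %d\n",
              length(x$care_plans), sum(x$resources$doctors$teams),
              sum(x$resources$planners$counts)))
  cat(sprintf("  pull-promoted sites: %s\n",
              if (length(x$policies$pull_sites_promoted))
                paste(x$policies$pull_sites_promoted, collapse = ", ")
              else "(baseline)"))
  invisible(x)
}
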