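SCENARIO_IDS <- c("baseline", "S1_spread_consultations",
                  "S2_no_ct_preallocation", "S3_balance_contouring",
                  "S4_p3_lung_chestwall", "S5_extra_p4_planner")

#' Scenario transforms
#'
#' Each scenario is a pure transform of the baseline configuration; the
#' baseline object is never mutated.
#'
#' * `transform_spread_consultations()` (S1) replaces each tumor site's five
#'   weekday arrival rates by their mean, preserving the weekly arrival mass
#'   per site exactly.
#' * `transform_no_ct_preallocation()` (S2) removes the IV-contrast and
#'   acute-reserved CT slot labels, so any patient can be booked into any
#'   free slot.
#' * `transform_balance_contouring()` (S3) re-arranges the doctors' agendas
#'   so each doctor has contouring time every day (at least two hours) while
#'   keeping the same weekly contouring minutes.
#' * `transform_skill_upgrade()` (S4) lets P3-level planners process the
#'   conventional plans of lung and chest-wall patients.
#' * `transform_extra_p4_planner()` (S5) adds one full-time P4-level
#'   planning RTT (able to do P4, P3 and P2).
#'
#' @param config an `rt_config`.
#' @return a new `rt_config`.
#' @export
transform_spread_consultations <- function(config) {
  rm_ <- config$arrivals$rate_matrix
  spread <- matrix(rowMeans(rm_), nrow(rm_), ncol(rm_),
                   dimnames = dimnames(rm_))
  config$arrivals$rate_matrix <- spread
  config$arrivals$weekday_totals[] <- colSums(spread)
  config
}

#' @rdname transform_spread_consultations
#' @export
transform_no_ct_preallocation <- function(config) {
  config$resources$ct$n_no_iv_slots <- 0L
  config$resources$ct$acute_reserved_per_day <- 0L
  config
}

#' @rdname transform_spread_consultations
#' @export
transform_balance_contouring <- function(config) {
  config$resources$doctors$agenda <- "balanced"
  config
}

#' @rdname transform_spread_consultations
#' @export
transform_skill_upgrade <- function(config) {
  config$policies$p3_extra_sites <-
    sort(unique(c(config$policies$p3_extra_sites, "lung", "chest_wall")))
  config
}

#' @rdname transform_spread_consultations
#' @export
transform_extra_p4_planner <- function(config) {
  config$resources$planners$counts[["P4"]] <-
    config$resources$planners$counts[["P4"]] + 1L
  config
}

#' @rdname transform_spread_consultations
#' @param scenario a scenario id (see `SCENARIO_IDS` below).
#' @export
scenario_transform <- function(config, scenario) {
  switch(scenario,
         baseline = config,
         S1_spread_consultations = transform_spread_consultations(config),
         S2_no_ct_preallocation = transform_no_ct_preallocation(config),
         S3_balance_contouring = transform_balance_contouring(config),
         S4_p3_lung_chestwall = transform_skill_upgrade(config),
         S5_extra_p4_planner = transform_extra_p4_planner(config),
         stop(sprintf("invalid scenario id '%s' (valid: %s)", scenario,
                      paste(SCENARIO_IDS, collapse = ", "))))
}

#' Aggregate per-replication KPIs
#'
#' @param reps data.frame of per-replication KPI rows.
#' @param alpha significance level for the t-based confidence interval.
#' @return data.frame with one row per KPI: mean, sd, CI bounds, min, max.
#' @export
summarize_replications <- function(reps, alpha = 0.05) {
  num <- reps[vapply(reps, is.numeric, NA)]
  n <- nrow(num)
  tcrit <- if (n >= 2) stats::qt(1 - alpha / 2, df = n - 1) else NA_real_
  out <- lapply(names(num), function(k) {
    x <- num[[k]]
    h <- if (n >= 2) tcrit * stats::sd(x) / sqrt(n) else NA_real_
    data.frame(kpi = k, mean = mean(x), sd = stats::sd(x),
               ci_lo = mean(x) - h, ci_hi = mean(x) + h,
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run a replicated experiment for one scenario
#'
#' Applies the scenario transform, runs `n_replications` independent
#' replications (each with its warm-up and measured horizon) and aggregates
#' the KPIs with t-based 95% confidence intervals. Replication `r` of every
#' scenario uses the same substream seeds (common random numbers), so
#' scenario differences are not confounded by different draws in untouched
#' components.
#'
#' @param config baseline `rt_config`.
#' @param scenario scenario id (default `"baseline"`).
#' @param n_replications number of replications (default from the config).
#' @param seed base seed.
#' @param warmup_days,horizon_days optional overrides.
#' @return an `rt_experiment`: `scenario`, `replications` (per-replication
#'   KPI data.frame), `aggregate` (from [summarize_replications()]).
#' @export
run_experiment <- function(config, scenario = "baseline",
                           n_replications = NULL, seed = 1L,
                           warmup_days = NULL, horizon_days = NULL) {
  if (is.null(n_replications)) {
    n_replications <- config$experiment$replications
  }
  if (n_replications < 2) stop("need at least 2 replications")
  cfg <- scenario_transform(config, scenario)
  reps <- vector("list", n_replications)
  for (r in seq_len(n_replications)) {
    sim <- simulate_rt(cfg, seed = seed, replication = r,
                       warmup_days = warmup_days,
                       horizon_days = horizon_days)
    row <- kpi_summary(sim, cfg)
    row$replication <- r
    reps[[r]] <- row
  }
  reps <- do.call(rbind, reps)
  out <- list(scenario = scenario, replications = reps,
              aggregate = summarize_replications(reps), seed = seed)
  class(out) <- "rt_experiment"
  out
}

#' @export
print.rt_experiment <- function(x, ...) {
  cat(sprintf("<rt_experiment> scenario %s, %d replications\n", x$scenario,
              nrow(x$replications)))
  agg <- x$aggregate
  for (k in c("mean_wt", "breaches", "rebooks", "pull_fraction")) {
    row <- agg[agg$kpi == k, ]
    cat(sprintf("  %-14s %7.2f (95%% CI %.2f, %.2f)\n", k, row$mean,
                row$ci_lo, row$ci_hi))
  }
  invisible(x)
}

#' Default nested pull sweep
#'
#' Cumulative promotion of tumor sites to the pull strategy, ordered from
#' the simplest to the most complex pre-treatment pathways under the
#' default catalogue; the first point is the baseline (no promotion), the
#' last promotes every site, giving 100% pull.
#'
#' @param config an `rt_config`.
#' @param steps optional indices into the full 0..8-site nesting, e.g.
#'   `c(0, 4, 8)` for baseline, half, all.
#' @return list of character vectors of promoted sites.
#' @export
default_sweep <- function(config, steps = 0:length(config$sweep_order)) {
  lapply(steps, function(k) config$sweep_order[seq_len(k)])
}

#' Workflow-control sweep: promote tumor sites to pull
#'
#' Runs one replicated experiment per sweep point under common random
#' numbers and collects the realized pull fraction, mean waiting time,
#' breach and rebook counts (mean, 95% CI, min, max) — the data behind the
#' pull-fraction box plots.
#'
#' @param config baseline `rt_config`.
#' @param sweep list of promoted-site sets, nested (each step adds sites);
#'   defaults to [default_sweep()].
#' @inheritParams run_experiment
#' @return an `rt_sweep`: `points` data.frame plus the full experiment
#'   objects.
#' @export
run_pull_sweep <- function(config, sweep = NULL, n_replications = NULL,
                           seed = 1L, warmup_days = NULL,
                           horizon_days = NULL) {
  if (is.null(sweep)) sweep <- default_sweep(config)
  for (i in seq_along(sweep)[-1]) {
    if (!all(sweep[[i - 1]] %in% sweep[[i]])) {
      stop("sweep must be nested: each step adds tumor sites")
    }
  }
  runs <- vector("list", length(sweep))
  rows <- vector("list", length(sweep))
  for (i in seq_along(sweep)) {
    cfg <- config
    cfg$policies$pull_sites_promoted <- sweep[[i]]
    ex <- run_experiment(cfg, "baseline", n_replications, seed,
                         warmup_days, horizon_days)
    runs[[i]] <- ex
    agg <- ex$aggregate
    pick <- function(k, f) agg[agg$kpi == k, f]
    rows[[i]] <- data.frame(
      point = i, n_promoted = length(sweep[[i]]),
      promoted = paste(sweep[[i]], collapse = "+"),
      pull_pct = 100 * pick("pull_fraction", "mean"),
      mean_wt = pick("mean_wt", "mean"),
      wt_lo = pick("mean_wt", "ci_lo"), wt_hi = pick("mean_wt", "ci_hi"),
      breaches = pick("breaches", "mean"),
      breaches_lo = pick("breaches", "ci_lo"),
      breaches_hi = pick("breaches", "ci_hi"),
      rebooks = pick("rebooks", "mean"),
      rebooks_lo = pick("rebooks", "ci_lo"),
      rebooks_hi = pick("rebooks", "ci_hi"),
      stringsAsFactors = FALSE
    )
  }
  out <- list(points = do.call(rbind, rows), runs = runs, seed = seed)
  class(out) <- "rt_sweep"
  out
}

#' @export
print.rt_sweep <- function(x, ...) {
  cat("<rt_sweep>\n")
  print(x$points[c("n_promoted", "pull_pct", "mean_wt", "breaches",
                   "rebooks")], row.names = FALSE)
  invisible(x)
}

#' Write experiment outputs to a directory
#'
#' Emits the per-replication KPI table as CSV and the aggregate (means and
#' 95% confidence intervals) as JSON.
#'
#' @param experiment an `rt_experiment`.
#' @param dir output directory (created if missing).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(experiment$replications,
                   file.path(dir, sprintf("replications_%s.csv",
                                          experiment$scenario)),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenario = experiment$scenario,
         aggregate = experiment$aggregate),
    file.path(dir, sprintf("aggregate_%s.json", experiment$scenario)),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Box-plot style figure of a pull sweep
#'
#' @param sweep an `rt_sweep`.
#' @param kpi which KPI to plot.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_sweep <- function(sweep, kpi = c("mean_wt", "breaches", "rebooks")) {
  kpi <- match.arg(kpi)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  pts <- sweep$points
  lo <- pts[[paste0(sub("mean_", "", kpi), "_lo")]]
  hi <- pts[[paste0(sub("mean_", "", kpi), "_hi")]]
  if (kpi == "mean_wt") { lo <- pts$wt_lo; hi <- pts$wt_hi }
  df <- data.frame(pull_pct = pts$pull_pct, y = pts[[kpi]], lo = lo, hi = hi)
  ggplot2::ggplot(df, ggplot2::aes(x = pull_pct, y = y)) +
    ggplot2::geom_crossbar(ggplot2::aes(ymin = lo, ymax = hi),
                           width = 2, fill = "grey80") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "patients scheduled in a pull manner (%)", y = kpi)
}
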