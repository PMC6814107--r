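#' Waiting times in calendar days
#'
#' Waiting time is the time needed to complete the pre-treatment phase:
#' calendar days (weekends included) from consultation to the first
#' irradiation session. A medically intended planned delay shifts the whole
#' countdown, so by default it is excluded from the waiting time (the
#' `kpi$waiting_time_excludes_planned_delay` switch restores the raw
#' difference). Patients still in progress at the horizon get `NA` and are
#' counted separately.
#'
#' @param patients the `patients` data.frame of an `rt_sim`.
#' @param config an `rt_config`.
#' @return numeric vector of calendar days, `NA` for work-in-progress.
#' @export
waiting_time <- function(patients, config) {
  wt <- patients$actual_start_day - patients$arrival_day
  if (isTRUE(config$kpi$waiting_time_excludes_planned_delay)) {
    wt <- wt - 7L * patients$delay_weeks
  }
  if (any(wt < 0, na.rm = TRUE)) stop("negative waiting time: audit the run")
  wt
}

#' Count waiting-time target breaches
#'
#' The national maxima are 1 calendar day for acute, 10 for subacute and 28
#' for regular patients; "within" is inclusive, so a breach is a waiting
#' time strictly greater than the target.
#'
#' @param wt waiting times from [waiting_time()].
#' @param urgency urgency class per patient.
#' @param targets named targets in days.
#' @return integer breach count (work-in-progress patients are not counted).
#' @export
count_breaches <- function(wt, urgency, targets) {
  sum(wt > unname(targets[urgency]), na.rm = TRUE)
}

#' KPI summary of one replication
#'
#' Restricts to patients whose arrival falls in the measured window (after
#' the warm-up, within the horizon) and reports mean waiting time overall
#' and by strategy, breach and rebook counts, and the work-in-progress
#' count.
#'
#' @param sim an `rt_sim`.
#' @param config the configuration the run used.
#' @return one-row data.frame.
#' @export
kpi_summary <- function(sim, config) {
  p <- sim$patients
  lo <- sim$warmup_days
  hi <- sim$warmup_days + sim$horizon_days
  p <- p[p$arrival_day >= lo & p$arrival_day < hi, ]
  wt <- waiting_time(p, config)
  pull <- p$strategy == "pull"
  data.frame(
    n_patients = nrow(p),
    n_completed = sum(!is.na(wt)),
    n_wip = sum(is.na(wt)),
    mean_wt = mean(wt, na.rm = TRUE),
    mean_wt_pull = mean(wt[pull], na.rm = TRUE),
    mean_wt_push = mean(wt[!pull], na.rm = TRUE),
    breaches = count_breaches(wt, p$urgency, config$targets),
    rebooks = sum(p$rebooks),
    pull_fraction = mean(pull)
  )
}

#' Relative error of the confidence-interval halfwidth
#'
#' For replication means `x_1..x_n`, the halfwidth of the `1 - alpha`
#' confidence interval is `t_{n-1, 1-alpha/2} * s / sqrt(n)`; the relative
#' error is that halfwidth divided by the sample mean. Replication counts
#' are increased until this drops below the threshold (0.05 by default).
#'
#' @param values numeric vector of per-replication means (`n >= 2`).
#' @param alpha significance level (default 0.05, a 95% interval).
#' @return the relative error (non-negative scalar).
#' @export
replication_relative_error <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 2) stop("need at least 2 replications")
  xbar <- mean(values)
  if (xbar == 0) stop("relative error undefined for zero mean")
  stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(values) / sqrt(n) / xbar
}

#' Smallest replication count meeting a relative-error threshold
#'
#' Accumulates replications from `simulate_fn(i)` and returns the first `n`
#' (starting at 2) whose relative error falls below `gamma`.
#'
#' @param simulate_fn `function(replication_index)` returning one scalar
#'   (for example the replication's mean waiting time).
#' @param gamma relative-error threshold (default 0.05).
#' @param alpha significance level.
#' @param n_max give up after this many replications and report the best
#'   achieved.
#' @return list with `n`, `values`, `relative_error`, `converged`.
#' @export
required_replications <- function(simulate_fn, gamma = 0.05, alpha = 0.05,
                                  n_max = 50L) {
  if (gamma <= 0) stop("gamma must be positive")
  values <- c(simulate_fn(1L), simulate_fn(2L))
  n <- 2L
  repeat {
    re <- replication_relative_error(values, alpha)
    if (re < gamma) {
      return(list(n = n, values = values, relative_error = re,
                  converged = TRUE))
    }
    if (n >= n_max) {
      return(list(n = n, values = values, relative_error = re,
                  converged = FALSE))
    }
    n <- n + 1L
    values <- c(values, simulate_fn(n))
  }
}

#' Warm-up curve: cumulative average waiting time over start days
#'
#' Orders patients by start day and tracks the cumulative mean waiting
#' time; the plateau estimate is the first day after which the cumulative
#' mean stays within a band of the final value, which is how the length of
#' the warm-up period is read off.
#'
#' @param start_day treatment start day per patient.
#' @param wt waiting time per patient.
#' @param band relative band around the final value (default 2%).
#' @return list with `curve` (data.frame `day`, `cum_mean`) and
#'   `plateau_day`.
#' @export
warmup_curve <- function(start_day, wt, band = 0.02) {
  keep <- !is.na(start_day) & !is.na(wt)
  start_day <- start_day[keep]; wt <- wt[keep]
  if (!length(start_day) || diff(range(start_day)) < 30) {
    stop("need at least 30 days of completed patients for a warm-up curve")
  }
  o <- order(start_day)
  start_day <- start_day[o]; wt <- wt[o]
  cum <- cumsum(wt) / seq_along(wt)
  last_per_day <- !duplicated(start_day, fromLast = TRUE)
  curve <- data.frame(day = start_day[last_per_day],
                      cum_mean = cum[last_per_day])
  final <- curve$cum_mean[nrow(curve)]
  inside <- abs(curve$cum_mean - final) <= band * abs(final)
  ok_after <- rev(cumprod(rev(inside))) > 0
  plateau <- curve$day[which(ok_after)[1]]
  list(curve = curve, plateau_day = plateau)
}
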