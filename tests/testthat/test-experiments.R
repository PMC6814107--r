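test_that("spreading consultations preserves weekly mass per site", {
  cfg <- default_config()
  before <- cfg$arrivals$rate_matrix
  cfg2 <- transform_spread_consultations(cfg)
  after <- cfg2$arrivals$rate_matrix
  # each row becomes its mean: (10,20,30,20,20) -> 20 everywhere
  expect_true(all(abs(after - rowMeans(before)) < 1e-12))
  expect_equal(rowSums(after), rowSums(before))
  # idempotent on an already-uniform config
  cfg3 <- transform_spread_consultations(cfg2)
  expect_equal(cfg3$arrivals$rate_matrix, cfg2$arrivals$rate_matrix)
  # the baseline object is never mutated
  expect_equal(cfg$arrivals$rate_matrix, before)
})

test_that("scenario transforms change exactly their own levers", {
  cfg <- default_config()
  s2 <- scenario_transform(cfg, "S2_no_ct_preallocation")
  expect_equal(s2$resources$ct$n_no_iv_slots, 0L)
  expect_equal(s2$resources$ct$acute_reserved_per_day, 0L)
  expect_equal(s2$arrivals, cfg$arrivals)
  s3 <- scenario_transform(cfg, "S3_balance_contouring")
  expect_equal(s3$resources$doctors$agenda, "balanced")
  s4 <- scenario_transform(cfg, "S4_p3_lung_chestwall")
  expect_setequal(s4$policies$p3_extra_sites, c("lung", "chest_wall"))
  expect_equal(s4$resources$planners$counts,
               cfg$resources$planners$counts)
  s5 <- scenario_transform(cfg, "S5_extra_p4_planner")
  expect_equal(s5$resources$planners$counts[["P4"]],
               cfg$resources$planners$counts[["P4"]] + 1L)
  roster5 <- build_planner_roster(s5)
  expect_equal(nrow(roster5), 25L)
  expect_equal(roster5$capacity[nrow(roster5)], 2L)
  expect_identical(scenario_transform(cfg, "baseline"), cfg)
  expect_error(scenario_transform(cfg, "S9_nonsense"), "invalid scenario")
})

test_that("the skill upgrade opens the lung and chest-wall share of work", {
  cfg <- default_config()
  # lung + chest wall make up 16.4% of arrivals under the default mix
  expect_equal(unname(sum(site_shares(cfg)[c("lung", "chest_wall")])),
               0.164, tolerance = 1e-9)
  pop <- sample_patients(cfg, 20000, seed = 4)
  roster <- build_planner_roster(cfg)
  servable <- function(extra) {
    p3 <- roster$skill[roster$skill == "P3"][1]
    vapply(seq_len(nrow(pop)), function(i)
      skill_covers("P3", pop$planning_type[i], pop$site[i], extra), NA)
  }
  base <- servable(character())
  upg <- servable(c("lung", "chest_wall"))
  gained <- upg & !base
  # the gain is exactly the P4-planned lung/chest-wall patients
  expect_true(all(pop$site[gained] %in% c("lung", "chest_wall")))
  expect_true(all(pop$planning_type[gained] == "P4"))
  expect_false(any(gained & pop$site == "breast"))
  expect_gt(mean(gained), 0.10)
})

test_that("experiments are deterministic and aggregate with t intervals", {
  cfg <- micro_config()
  cfg$arrivals$rate_matrix["breast", ] <- 3
  cfg$arrivals$weekday_totals[] <- 3
  e1 <- run_experiment(cfg, "baseline", n_replications = 2, seed = 5,
                       warmup_days = 5, horizon_days = 20)
  e2 <- run_experiment(cfg, "baseline", n_replications = 2, seed = 5,
                       warmup_days = 5, horizon_days = 20)
  expect_identical(e1$aggregate, e2$aggregate)
  expect_error(run_experiment(cfg, "baseline", n_replications = 1),
               "at least 2")
  # aggregate columns follow the t-based halfwidth
  agg <- e1$aggregate
  r <- e1$replications$mean_wt
  h <- qt(0.975, 1) * sd(r) / sqrt(2)
  row <- agg[agg$kpi == "mean_wt", ]
  expect_equal(row$mean, mean(r))
  expect_equal(row$ci_hi - row$mean, h, tolerance = 1e-9)
  expect_equal(row$min, min(r))
})

test_that("common random numbers isolate the effect of pull promotion", {
  cfg <- default_config()
  cfg2 <- cfg
  cfg2$policies$pull_sites_promoted <- "breast"
  a <- simulate_rt(cfg, seed = 6, warmup_days = 0, horizon_days = 20)
  b <- simulate_rt(cfg2, seed = 6, warmup_days = 0, horizon_days = 20)
  pa <- a$patients; pb <- b$patients
  expect_equal(nrow(pa), nrow(pb))
  # identical case mix: sites, plans, urgencies, steps, planning types
  for (col in c("site", "plan", "urgency", "planning_type", "mri", "petct",
                "warping", "image_registration", "delay_weeks",
                "combined")) {
    expect_identical(pa[[col]], pb[[col]])
  }
  # strategy flips only for breast regular non-combined patients
  flipped <- pa$strategy != pb$strategy
  expect_true(all(pa$site[flipped] == "breast"))
  expect_true(all(pa$strategy[flipped] == "push" &
                    pb$strategy[flipped] == "pull"))
})

test_that("the pull sweep is nested, reproducible and spans 40-100%", {
  cfg <- default_config()
  sw <- default_sweep(cfg)
  expect_length(sw, 9L)
  expect_length(sw[[1]], 0L)
  expect_setequal(sw[[9]], TUMOR_SITES)
  expect_error(
    run_pull_sweep(cfg, sweep = list("breast", "lung"),
                   n_replications = 2, warmup_days = 2, horizon_days = 5),
    "nested")
  sw3 <- run_pull_sweep(cfg, sweep = default_sweep(cfg, c(0, 8)),
                        n_replications = 2, seed = 2, warmup_days = 5,
                        horizon_days = 25)
  expect_equal(nrow(sw3$points), 2L)
  expect_equal(sw3$points$pull_pct[2], 100)
  expect_gt(sw3$points$pull_pct[1], 30)
  expect_lt(sw3$points$pull_pct[1], 50)
  # the first point equals a plain baseline run with the same seeds
  base <- run_experiment(cfg, "baseline", n_replications = 2, seed = 2,
                         warmup_days = 5, horizon_days = 25)
  expect_equal(sw3$runs[[1]]$aggregate, base$aggregate)
  # 100% pull produces strictly positive rebooks
  expect_gt(sw3$points$rebooks[2], 0)
})

test_that("experiment outputs serialise to CSV and JSON", {
  cfg <- micro_config()
  cfg$arrivals$rate_matrix["breast", ] <- 2
  cfg$arrivals$weekday_totals[] <- 2
  ex <- run_experiment(cfg, "baseline", n_replications = 2, seed = 1,
                       warmup_days = 2, horizon_days = 10)
  dir <- tempfile()
  write_experiment(ex, dir)
  reps <- utils::read.csv(file.path(dir, "replications_baseline.csv"))
  expect_equal(nrow(reps), 2L)
  agg <- jsonlite::fromJSON(file.path(dir, "aggregate_baseline.json"))
  expect_equal(agg$scenario, "baseline")
  expect_true("mean_wt" %in% agg$aggregate$kpi)
})
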