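# Deterministic micro-scenarios: single patients with degenerate randomness
# whose milestone times are hand-traced. The fixture uses a one-doctor team
# with a daily 10:00-13:09 contouring block, consults at 08:00 sharp, CT
# slots every 45 minutes from 07:30, and point-mass policy tables.

test_that("a push patient's trajectory matches the hand-traced milestones", {
  cfg <- micro_config(urgency = "regular", planning_type = "P3",
                      planning_minutes = 240L, push_gap_day = 2L)
  sim <- micro_sim(cfg, days = 0L)
  p <- sim$patients
  expect_equal(nrow(p), 1L)
  expect_equal(p$strategy, "push")
  # CT: first admissible slot after the 08:00 consult starts 08:15
  expect_equal(p$ct_end, sim_time(0) + 495 + 25)
  expect_equal(p$last_scan, p$ct_end)           # no other scans
  expect_equal(p$ipp_done, p$last_scan)         # no post-processing
  # contouring: 120 min in the 10:00 block of the only breast doctor
  expect_equal(p$contour_start, sim_time(0, 10))
  expect_equal(p$contour_done, sim_time(0, 12))
  # planning starts immediately (idle planners) and runs 240 min
  expect_equal(p$plan_start, sim_time(0, 12))
  expect_equal(p$plan_done, sim_time(0, 16))
  # push start = planning-start day + forced 2-day gap
  expect_equal(p$sched_start_day, 2L)
  expect_equal(p$actual_start_day, 2L)
  expect_equal(p$rebooks, 0L)
  expect_equal(waiting_time(p, cfg), 2)
})

test_that("a pull patient with ample time starts as scheduled, no rebooks", {
  cfg <- micro_config(urgency = "subacute", planning_type = "P2",
                      planning_minutes = 60L, ttt_day = 4L)
  sim <- micro_sim(cfg, days = 0L)
  p <- sim$patients
  expect_equal(p$strategy, "pull")
  # subacute contour 30 + 60 peer review = 90 min from 10:00
  expect_equal(p$contour_done - p$contour_start, 90)
  expect_equal(p$plan_done, p$contour_done + 60)
  expect_equal(p$sched_start_day, 4L)
  expect_equal(p$actual_start_day, 4L)
  expect_equal(p$rebooks, 0L)
  expect_equal(waiting_time(p, cfg), 4)
})

test_that("an unfinished plan triggers day-by-day rebooks until completion", {
  cfg <- micro_config(urgency = "subacute", planning_type = "P4",
                      planning_minutes = 1200L, ttt_day = 1L)
  sim <- micro_sim(cfg, days = 0L)
  p <- sim$patients
  # contour 10:00-11:30; planning 1200 min: 330 left on day 0 (till 17:00),
  # 540 on day 1, finishing 330 min into day 2 => 13:30
  expect_equal(p$plan_done, sim_time(2, 13, 30))
  # scheduled day 1; checkpoint on day 0 17:30 postpones to day 2;
  # checkpoint on day 1 postpones to day 3; start 16:00 day 3
  expect_equal(p$sched_start_day, 3L)
  expect_equal(p$rebooks, 2L)
  expect_equal(p$actual_start_day, 3L)
  expect_equal(waiting_time(p, cfg), 3)
})

test_that("head-and-neck rebooks jump to the following Monday", {
  cfg <- micro_config(urgency = "subacute", planning_type = "P4",
                      planning_minutes = 1200L, ttt_day = 7L,
                      start_weekday = 1L)
  sim <- micro_sim(cfg, days = 0L)  # Monday arrival, start next Monday
  p <- sim$patients
  expect_equal(p$sched_start_day, 7L)
  expect_equal(p$actual_start_day, 7L)
  expect_equal(p$rebooks, 0L)
  # now make planning impossible before day 7: 8 working days of 540 min
  cfg2 <- micro_config(urgency = "subacute", planning_type = "P4",
                       planning_minutes = 540L * 8L, ttt_day = 7L,
                       start_weekday = 1L)
  p2 <- micro_sim(cfg2, days = 0L)$patients
  expect_equal(p2$sched_start_day, 14L)   # rebooked a full week
  expect_equal(p2$rebooks, 1L)
  expect_equal(day_weekday(p2$actual_start_day), 1L)
})

test_that("contouring queue serves the earliest due date first", {
  cfg <- micro_config(urgency = "subacute", planning_type = "P2",
                      planning_minutes = 60L)
  # two subacute pull patients, same Monday; the daily block fits exactly
  # two 90-min contours, so dispatch order is observable in start times
  cfg$policies$ttt$subacute <- list(support = c(3L, 4L), weights = c(.5, .5))
  sim <- micro_sim(cfg, days = c(0L, 0L), seed = 2)
  p <- sim$patients
  expect_equal(nrow(p), 2L)
  ord_due <- order(p$sched_start_day, p$id)
  ord_serve <- order(p$contour_start)
  expect_equal(ord_serve, ord_due)
  # brute-force oracle on the single 189-min block from 10:00: the earlier
  # due contour runs 10:00-11:30, the other 11:30-13:00
  expect_equal(sort(sim_tod(p$contour_start)), c(600, 690))
})

test_that("EDD completion times match a brute-force queue simulation", {
  # one doctor, K same-day subacute pull patients with distinct due dates:
  # the package's dispatch must equal a naive EDD simulation over the
  # doctor's daily blocks
  K <- 5L
  cfg <- micro_config(urgency = "subacute", planning_type = "P2",
                      planning_minutes = 60L)
  cfg$policies$ttt$subacute <- list(support = 1:8, weights = rep(1 / 8, 8))
  sim <- micro_sim(cfg, days = rep(0L, K), seed = 6)
  p <- sim$patients
  # event-driven oracle: at every decision instant (block opening, task
  # completion, task becoming ready at an idle doctor) serve the ready task
  # with the earliest due date; blocks are [10:00, 13:09), 90 min per task,
  # non-preemptive and work-conserving
  ready <- p$ipp_done
  due <- p$sched_start_day
  starts <- rep(NA_real_, K)
  pending <- seq_len(K)
  day <- 0L
  t <- sim_time(day, 10)
  while (length(pending)) {
    block_end <- sim_time(day, 10) + 189L
    if (t + 90L > block_end) {
      day <- next_workday(day)
      t <- sim_time(day, 10)
      next
    }
    ready_now <- pending[ready[pending] <= t]
    if (length(ready_now)) {
      i <- ready_now[order(due[ready_now], ready_now)][1]
      starts[i] <- t
      t <- t + 90L
      pending <- setdiff(pending, i)
    } else {
      t <- max(t, min(ready[pending]))
    }
  }
  expect_equal(p$contour_start, starts)
})

test_that("planner concurrency allows two plans, queues the third", {
  cfg <- micro_config(urgency = "subacute", planning_type = "P4",
                      planning_minutes = 300L, ttt_day = 8L)
  # a single P4 planner
  cfg$resources$planners$counts <- c(P2 = 0L, P3 = 0L, P4 = 1L)
  # contour 90 min each from 10:00 in one 189-min block: ready at 11:30,
  # 13:00, then next day 11:30
  sim <- micro_sim(cfg, days = rep(0L, 3L), seed = 3)
  p <- sim$patients[order(sim$patients$contour_done), ]
  # first two plans run concurrently on the one planner
  expect_equal(p$plan_start[1], p$contour_done[1])
  expect_equal(p$plan_start[2], p$contour_done[2])
  expect_lt(p$plan_start[2], p$plan_done[1])
  # the third waits for a free token
  expect_gte(p$plan_start[3], min(p$plan_done[1], p$plan_done[2]))
})

test_that("downward compatibility serves a P2 task with only a P4 planner", {
  cfg <- micro_config(urgency = "subacute", planning_type = "P2",
                      planning_minutes = 60L, ttt_day = 6L)
  cfg$resources$planners$counts <- c(P2 = 0L, P3 = 0L, P4 = 1L)
  p <- micro_sim(cfg, days = 0L)$patients
  expect_false(is.na(p$plan_done))
  expect_equal(p$plan_done, p$contour_done + 60)
})

test_that("stage precedence and slot occupancy hold on a traced run", {
  cfg <- default_config()
  sim <- simulate_rt(cfg, seed = 8, warmup_days = 0, horizon_days = 40,
                     trace = TRUE)
  expect_true(audit_precedence(sim))
  # imaging occupies whole slots: CT milestones sit on slot ends
  ct_tods <- sim_tod(sim$patients$ct_end)
  slot_ends <- unique(sim_tod(build_slot_calendar(cfg, "ct", 7)$end))
  expect_true(all(ct_tods %in% slot_ends))
  # push patients never rebook
  expect_true(all(sim$patients$rebooks[sim$patients$strategy == "push"] ==
                    0L))
  # pull starts at/after the first scheduled date only through rebooks
  p <- sim$patients[!is.na(sim$patients$actual_start_day), ]
  no_rb <- p$rebooks == 0L
  expect_true(all(p$actual_start_day[no_rb] == p$sched_start_day[no_rb]))
})

test_that("work-in-progress patients are excluded from waiting times", {
  cfg <- default_config()
  sim <- simulate_rt(cfg, seed = 9, warmup_days = 0, horizon_days = 15)
  k <- kpi_summary(sim, cfg)
  expect_equal(k$n_completed + k$n_wip, k$n_patients)
  expect_gt(k$n_wip, 0)   # a 15-day window always leaves work in progress
})
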