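test_that("weekly slot supply matches the department capacities", {
  cfg <- default_config()
  cfg$holidays <- character()   # a holiday-free week
  ct <- build_slot_calendar(cfg, "ct", 7)
  mri <- build_slot_calendar(cfg, "mri", 7)
  pet <- build_slot_calendar(cfg, "petct", 7)
  expect_equal(length(ct$start), 130L)   # 26 per day x 5 days
  expect_equal(length(mri$start), 37L)
  expect_equal(length(pet$start), 5L)
  expect_true(all(sim_tod(ct$start) >= 450 & sim_tod(ct$end) <= 1050))
  expect_true(all(day_weekday(sim_day(ct$start)) <= 5))
  # per day: 26 CT slots, 4 IV-restricted (2 per scanner), 1 acute-reserved
  day0 <- sim_day(ct$start) == 0
  expect_equal(sum(day0), 26L)
  expect_equal(sum(ct$label[day0] == 1L), 4L)
  expect_equal(sum(ct$label[day0] == 2L), 1L)
})

test_that("earliest-slot search respects labels and bookings", {
  cfg <- default_config()
  cfg$holidays <- character()
  cal <- build_slot_calendar(cfg, "ct", 10)
  # an unrestricted patient gets the chronologically first slot
  s1 <- find_earliest_slot(cal, sim_time(0), book = FALSE)
  expect_equal(s1$start, sim_time(0) + 450)
  # IV-contrast patients skip the first two morning slots of each scanner
  s2 <- find_earliest_slot(cal, sim_time(0), iv_contrast = TRUE,
                           book = FALSE)
  expect_true(cal$label[s2$index] == 0L)
  expect_gt(s2$start, s1$start)
  # the acute-reserved slot only admits acute patients
  cal2 <- build_slot_calendar(cfg, "ct", 10)
  cal2$booked[cal2$label != 2L & sim_day(cal2$start) == 0] <- TRUE
  nonacute <- find_earliest_slot(cal2, sim_time(0), acute = FALSE,
                                 book = FALSE)
  expect_equal(sim_day(nonacute$start), 1L)       # pushed to the next day
  acute <- find_earliest_slot(cal2, sim_time(0), acute = TRUE, book = FALSE)
  expect_equal(sim_day(acute$start), 0L)
  expect_equal(cal2$label[acute$index], 2L)
  # booking consumes the slot
  b <- find_earliest_slot(cal, sim_time(0), book = TRUE)
  b2 <- find_earliest_slot(cal, sim_time(0), book = TRUE)
  expect_gt(b2$start, b$start - 1)
  expect_true(b2$index != b$index)
  # exhausted horizon signals a capacity misconfiguration
  cal$booked[] <- TRUE
  expect_error(find_earliest_slot(cal, sim_time(0), horizon_days = 5),
               "capacity misconfiguration")
})

test_that("booked slot search matches an exhaustive oracle", {
  cfg <- default_config()
  cal <- build_slot_calendar(cfg, "ct", 30)
  set.seed(11)
  cal$booked <- runif(length(cal$start)) < 0.6
  for (i in 1:50) {
    earliest <- sim_time(sample.int(20, 1), sample.int(17, 1))
    acute <- runif(1) < 0.2
    iv <- runif(1) < 0.3
    got <- find_earliest_slot(cal, earliest, acute, iv, book = FALSE)
    ok <- !cal$booked & cal$start >= earliest &
      (cal$label == 0L | (cal$label == 1L & !iv) | (cal$label == 2L & acute))
    expect_equal(got$index, which(ok)[1])
  }
})

test_that("removing CT pre-allocation never worsens any booking", {
  cfg <- default_config()
  cfg2 <- transform_no_ct_preallocation(cfg)
  cal_a <- build_slot_calendar(cfg, "ct", 10)
  cal_b <- build_slot_calendar(cfg2, "ct", 10)
  expect_true(all(cal_b$label == 0L))
  set.seed(3)
  for (i in 1:40) {
    earliest <- sim_time(sample.int(5, 1), sample.int(10, 1))
    acute <- runif(1) < 0.2; iv <- runif(1) < 0.5
    a <- find_earliest_slot(cal_a, earliest, acute, iv, book = FALSE)
    b <- find_earliest_slot(cal_b, earliest, acute, iv, book = FALSE)
    expect_lte(b$start, a$start)   # feasibility monotonicity
  }
})

test_that("doctor agendas expose disjoint in-shift free intervals", {
  cfg <- default_config()
  cfg$holidays <- character()
  ag <- build_agendas(cfg, 40, rng = NULL)
  expect_equal(length(ag), 44L)
  counts <- table(vapply(ag, `[[`, "", "team"))
  expect_equal(as.integer(counts[c("Lung", "HeadNeck", "Breast", "CNS",
                                   "Gynecology", "GI", "Urology")]),
               c(7L, 9L, 9L, 3L, 4L, 5L, 7L))
  for (a in ag[c(1, 10, 25, 44)]) {
    for (day in 0:13) {
      iv <- doctor_free_intervals(a, day)
      if (!is_workday(day)) expect_equal(nrow(iv), 0L)
      if (nrow(iv)) {
        expect_true(all(iv[, 1] < iv[, 2]))
        expect_true(all(sim_tod(iv[, 1]) >= a$shift[1] &
                          sim_tod(iv[, 2]) <= a$shift[2]))
        if (nrow(iv) > 1) expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2]))
      }
    }
  }
})

test_that("absence days empty the agenda", {
  cfg <- default_config()
  ag <- build_agendas(cfg, 20, rng = NULL)[[1]]
  ag$absent_days <- 1L
  expect_equal(nrow(doctor_free_intervals(ag, 1)), 0L)
})

test_that("balancing contouring preserves weekly minutes with >= 2h daily", {
  cfg <- default_config()
  cfg$holidays <- character()
  week_minutes <- function(agenda) {
    sum(vapply(0:4, function(d) {
      iv <- doctor_free_intervals(agenda, d)
      if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0
    }, 0))
  }
  a_clustered <- build_agendas(cfg, 10, rng = NULL)
  a_balanced <- build_agendas(transform_balance_contouring(cfg), 10,
                              rng = NULL)
  for (i in c(1, 7, 20, 44)) {
    expect_equal(week_minutes(a_balanced[[i]]),
                 week_minutes(a_clustered[[i]]))
    daily <- vapply(0:4, function(d) {
      iv <- doctor_free_intervals(a_balanced[[i]], d)
      sum(iv[, 2] - iv[, 1])
    }, 0)
    expect_true(all(daily >= 120))
  }
})

test_that("planner skills are downward compatible with concurrency limits", {
  cfg <- default_config()
  roster <- build_planner_roster(cfg)
  expect_equal(nrow(roster), 24L)
  expect_equal(as.integer(table(roster$skill)[c("P2", "P3", "P4")]),
               c(3L, 7L, 14L))
  expect_equal(nrow(build_planner_roster(
    default_config(planner_preset = "enumerated"))), 20L)
  expect_equal(unname(roster$capacity[roster$skill == "P2"][1]), 1L)
  expect_equal(unname(roster$capacity[roster$skill == "P4"][1]), 2L)
  # downward compatibility (and its transitivity P4 -> P3 -> P2)
  expect_true(skill_covers("P4", "P2"))
  expect_true(skill_covers("P4", "P3"))
  expect_true(skill_covers("P3", "P2"))
  expect_false(skill_covers("P3", "P4"))
  expect_false(skill_covers("P2", "P3"))
  # a P4 task with only a P2-level roster finds nobody
  p2only <- roster[roster$skill == "P2", ]
  expect_length(eligible_planners("P4", p2only), 0L)
  # every planner is eligible for a P2 task
  expect_length(eligible_planners("P2", roster), 24L)
  # concurrency tokens exclude saturated planners
  busy <- integer(24); busy[roster$skill == "P4"] <- 2L
  expect_false(any(roster$skill[eligible_planners("P4", roster, busy)] ==
                     "P4"))
  # the skill-upgrade scenario opens P4 lung tasks to P3 planners
  expect_true(all(c("P3", "P4") %in%
    roster$skill[eligible_planners("P4", roster, site = "lung",
                                   p3_extra_sites = c("lung",
                                                      "chest_wall"))]))
  expect_false("P3" %in%
    roster$skill[eligible_planners("P4", roster, site = "breast",
                                   p3_extra_sites = c("lung",
                                                      "chest_wall"))])
})
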