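test_that("the reference process has the expected structure", {
  proc <- fixture_pathology_process()
  acts <- proc$activities
  expect_equal(nrow(acts), 36L)
  expect_setequal(unique(acts$category), activity_categories())
  expect_equal(sort(acts$id[acts$category == "inspection"]), c(3L, 12L))
  expect_equal(sort(acts$id[acts$placeholder]), c(1L, 2L, 6L, 35L, 36L))
  expect_true(all(acts$mean_min[acts$placeholder] == 0.5))
})

test_that("per-unit times reproduce the published weekly workload cells", {
  acts <- fixture_pathology_process()$activities
  printed <- acts[!acts$placeholder, ]
  # back out the weekly hours at 239 units and compare to 3 decimals
  expect_equal(round(printed$mean_min * 239 / 60, 3),
               round(printed$table7_hours, 3))
  expect_equal(acts$mean_min[acts$id == 13], 19.975 * 60 / 239,
               tolerance = 1e-9)
  expect_equal(acts$mean_min[acts$id == 13], 5.014, tolerance = 1e-3)
  expect_equal(acts$mean_min[acts$id == 34], 1.649, tolerance = 1e-3)
})

test_that("stochastic mode assigns a 20 percent SD, deterministic none", {
  det <- fixture_pathology_process()$activities
  sto <- fixture_pathology_process(stochastic = TRUE)$activities
  expect_true(all(det$sd_min == 0))
  expect_equal(sto$sd_min, 0.2 * sto$mean_min)
})

test_that("config round-trip through CSV + YAML is the identity", {
  proc <- fixture_pathology_process()
  dir <- tempfile("procdef")
  write_process(proc, dir)
  back <- load_process(dir)
  expect_equal(back$activities$id, proc$activities$id)
  expect_equal(back$activities$category, proc$activities$category)
  expect_equal(back$activities$mean_min, proc$activities$mean_min,
               tolerance = 1e-12)
  expect_equal(back$activities$resource, proc$activities$resource)
  expect_equal(back$resources, proc$resources)
  expect_equal(back$calendars[["weekday"]]$weekly_hours,
               proc$calendars[["weekday"]]$weekly_hours)
  # and the shipped config loads to the same process
  shipped <- load_process(system.file("extdata", "pathology_process",
                                      package = "pathflowsim"))
  expect_equal(nrow(shipped$activities), 36L)
  expect_setequal(unique(shipped$activities$category),
                  activity_categories())
})

test_that("validation rejects malformed definitions with named errors", {
  proc <- fixture_pathology_process()
  bad_cat <- proc$activities
  bad_cat$category[bad_cat$id == 16] <- "waitingg"
  expect_error(process_definition(bad_cat, proc$resources, proc$calendars),
               "waitingg.*16")
  bad_res <- proc$activities
  bad_res$resource[1] <- "ghost"
  expect_error(process_definition(bad_res, proc$resources, proc$calendars),
               "unknown resource: ghost")
  cyc <- proc$activities
  cyc$successor[cyc$id == 10] <- 3L
  expect_error(process_definition(cyc, proc$resources, proc$calendars),
               "cycle")
  dup <- rbind(proc$activities, proc$activities[1, ])
  expect_error(process_definition(dup, proc$resources, proc$calendars),
               "unique")
})

test_that("activity removal re-links the chain and guards the terminus", {
  proc <- fixture_pathology_process()
  trimmed <- remove_activities(proc, c(6L, 32L))
  expect_equal(nrow(trimmed$activities), 34L)
  # re-validation inside process_definition() proves the chain is connected
  expect_s3_class(trimmed, "process_definition")
  expect_equal(trimmed$activities$successor[trimmed$activities$id == 5L], 7L)
  expect_equal(trimmed$activities$successor[trimmed$activities$id == 31L], 33L)
  expect_identical(remove_activities(proc, integer(0)), proc)
  expect_error(remove_activities(proc, 99L), "unknown activity")
  expect_error(remove_activities(proc, 36L), "terminal")
})

test_that("shift calendars compute hours and reject bad windows", {
  cal <- shift_calendar(c("07:00-12:00", "13:00-16:00"), days_per_week = 5)
  expect_equal(cal$daily_hours, 8)
  expect_equal(cal$weekly_hours, 40)
  expect_error(shift_calendar("16:00-07:00"), "end after")
  expect_error(shift_calendar(c("07:00-12:00", "11:00-13:00")), "overlap")
})

test_that("utilization-based weekly capacity is set by the slowest station", {
  proc <- fixture_pathology_process()
  # activity 19 holds each unit 39.912 h / 239 units at 40 h per week
  expect_equal(weekly_capacity(proc), 40 / (39.912 / 239),
               tolerance = 1e-9)
  expect_equal(weekly_capacity(single_station(mean_min = 2, servers = 2)),
               40 * 60, tolerance = 1e-9)
})
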