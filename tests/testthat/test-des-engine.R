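test_that("a single saturated station processes all arrivals", {
  proc <- single_station(mean_min = 1, sd_min = 0, servers = 1L,
                         weekly_hours = 40)
  # 60 deterministic arrivals spread over the 40-h week, 1-min service:
  # with capacity to spare every unit completes and accrues 1 h of work
  sim <- run_simulation(proc, demand_spec(60, 0), horizon_hours = 40,
                        replicates = 1, seed = 3)
  expect_equal(sim$summary$arrivals, 60)
  expect_equal(sim$summary$completions, 60)
  expect_equal(sim$activity$busy_hours, 1, tolerance = 1e-9)
  expect_equal(sim$activity$utilization, 1 / 40, tolerance = 1e-9)
})

test_that("near-zero demand produces an idle system", {
  proc <- single_station()
  sim <- run_simulation(proc, demand_spec(1e-6, 0), 40, 1, seed = 1)
  expect_equal(sim$summary$completions, 0)
  expect_equal(sim$activity$utilization, 0)
  expect_equal(unname(category_totals(sim)), rep(0, 5))
})

test_that("entities are conserved in every replicate", {
  proc <- fixture_pathology_process(stochastic = TRUE)
  sim <- run_simulation(proc, demand_spec(), 40, replicates = 3, seed = 7)
  s <- sim$summary
  expect_equal(s$arrivals_total,
               s$completions_total + s$in_service + s$in_queue)
  a <- sim$activity
  expect_true(all(a$units_in >= a$units_out))
  expect_true(all(a$busy_hours >= 0 & a$queue_hours >= 0))
})

test_that("identical configuration and seed give identical event logs", {
  proc <- fixture_pathology_process(stochastic = TRUE)
  s1 <- run_simulation(proc, demand_spec(), 40, 2, seed = 42,
                       keep_log = TRUE)
  s2 <- run_simulation(proc, demand_spec(), 40, 2, seed = 42,
                       keep_log = TRUE)
  expect_identical(s1$event_log, s2$event_log)
  expect_identical(s1$activity, s2$activity)
  s3 <- run_simulation(proc, demand_spec(), 40, 2, seed = 43,
                       keep_log = TRUE)
  expect_false(identical(s1$event_log, s3$event_log))
})

test_that("adding a server to a congested station never cuts throughput", {
  for (seed in 1:3) {
    thr <- vapply(c(1L, 2L), function(k) {
      proc <- single_station(mean_min = 10, sd_min = 2, servers = k)
      # demand beyond one server's 240-unit weekly capacity
      sim <- run_simulation(proc, demand_spec(300, 20), 40, 2, seed = seed)
      mean(sim$summary$completions)
    }, numeric(1))
    expect_gte(thr[2], thr[1])
  }
})

test_that("a lightly loaded station satisfies Little's law", {
  proc <- single_station(mean_min = 2, sd_min = 0.4)
  sim <- run_simulation(proc, demand_spec(100, 10), horizon_hours = 200,
                        replicates = 1, seed = 5)
  s <- sim$summary
  lambda <- s$completions / 200            # per operational hour
  W <- s$mean_time_in_system_min / 60      # hours
  expect_equal(s$time_avg_wip, lambda * W, tolerance = 0.1)
})

test_that("bottleneck detection flags the workload-saturated activities", {
  proc <- fixture_pathology_process()
  sim <- run_simulation(proc, demand_spec(weekly_capacity(proc), 0),
                        horizon_hours = 40, replicates = 5, seed = 1,
                        warmup_hours = 40)
  hot <- find_bottlenecks(sim, threshold = 0.90)
  expect_setequal(as.integer(hot), c(19L, 32L, 33L))
  expect_equal(as.integer(hot)[1], 19L) # sorted by utilization
  util <- attr(hot, "utilization")
  expect_equal(util[match(19, hot)], 0.9978, tolerance = 0.05)
  expect_equal(util[match(32, hot)], 0.9371, tolerance = 0.05)
  expect_equal(util[match(33, hot)], 0.9238, tolerance = 0.05)
  expect_length(find_bottlenecks(sim, threshold = 1.5), 0)
  active <- unique(sim$activity$id[sim$activity$busy_hours > 0])
  expect_setequal(as.integer(find_bottlenecks(sim, threshold = 0)), active)
})

test_that("category totals mirror the published split and add up", {
  proc <- fixture_pathology_process()
  sim <- run_simulation(proc, demand_spec(weekly_capacity(proc), 0),
                        40, replicates = 5, seed = 1, warmup_hours = 40)
  tot <- category_totals(sim)
  expect_equal(unname(tot["inspection"]), 2.336 + 2.340, tolerance = 0.02)
  per_rep <- aggregate(busy_hours ~ replicate, sim$activity, sum)
  expect_equal(sum(tot), mean(per_rep$busy_hours), tolerance = 1e-9)
})

test_that("a resource without on-shift capacity is a configuration error", {
  proc <- single_station()
  proc$resources$servers <- 0L
  expect_error(run_simulation(proc, demand_spec(10, 0), 40, 1, seed = 1),
               "no on-shift capacity")
})
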