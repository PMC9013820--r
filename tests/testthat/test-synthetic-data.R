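test_that("generated logs carry the configured attribute mix", {
  cfg <- synthetic_config(weeks = 52, seed = 1)
  log <- generate_biopsy_log(cfg)
  expect_gt(nrow(log), 52 * 100)
  top4 <- c("gynecology", "general_surgery", "gastroenterology",
            "minor_surgery")
  expect_lt(abs(mean(log$specialty %in% top4) - 0.8124), 0.03)
  expect_lt(abs(mean(log$provenance == "own") - 0.87), 0.02)
  expect_true(all(log$cut_min > 0 & log$analysis_min > 0))
  dw <- log$diagnosed_week[!is.na(log$diagnosed_week)]
  expect_true(all(dw >= log$week[!is.na(log$diagnosed_week)]))
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- synthetic_config(weeks = 10, seed = 33)
  expect_identical(generate_biopsy_log(cfg), generate_biopsy_log(cfg))
  other <- generate_biopsy_log(synthetic_config(weeks = 10, seed = 34))
  expect_false(identical(generate_biopsy_log(cfg), other))
})

test_that("ample diagnosis capacity leaves nothing pending", {
  cfg <- synthetic_config(weeks = 30, diagnosis_capacity_per_week = 1e6,
                          seed = 2)
  log <- generate_biopsy_log(cfg)
  expect_equal(sum(is.na(log$diagnosed_week)), 0L)
  gs <- gap_series(log)
  expect_true(all(gs$gap == 0))
})

test_that("the received/diagnosed gap opens at the onset week and grows", {
  cfg <- synthetic_config(weeks = 52, seed = 3)
  gs <- gap_series(generate_biopsy_log(cfg))
  expect_true(all(gs$gap[gs$week < 24] == 0))
  after <- gs$gap[gs$week >= 24]
  expect_true(all(diff(after) > 0))
  expect_true(all(gs$gap >= 0))
  expect_true(all(diff(gs$received_cum) >= 0))
  expect_true(all(diff(gs$diagnosed_cum) >= 0))
  empty <- gap_series(generate_biopsy_log(
    synthetic_config(weeks = 1, demand = demand_spec(1e-6, 0), seed = 1)))
  expect_equal(nrow(empty), 0L)
})

test_that("a 43-week run reproduces the study's undiagnosed share", {
  cfg <- synthetic_config(weeks = 43, seed = 4)
  log <- generate_biopsy_log(cfg)
  pending <- mean(is.na(log$diagnosed_week))
  expect_lt(abs(pending - 0.38), 0.05)
})

test_that("weekly counts pass the normality screen across seeds", {
  accepted <- vapply(1:20, function(s) {
    log <- generate_biopsy_log(synthetic_config(weeks = 52, seed = s))
    counts <- tabulate(log$week, nbins = 52)
    normality_check(counts, alpha = 0.01)$accepted
  }, logical(1))
  expect_gte(mean(accepted), 0.95)
})

test_that("the recovery suite closes the generator/estimator loop", {
  rec <- recovery_suite(synthetic_config(weeks = 200, seed = 5))
  se <- 18.45 / sqrt(200)
  expect_lt(abs(rec$demand$est_mean - 151.55), 3 * se)
  expect_lt(abs(rec$analysis$est_proportions[1] - 0.648), 0.05)
  expect_lt(abs(rec$analysis$est_means[1] - 9.2571), 0.5)
  expect_lt(abs(rec$analysis$est_means[2] - 27.389), 0.5)
  expect_s3_class(rec$demand$normality, "normality_result")
  expect_s3_class(rec$demand$gof, "gof_result")
})

test_that("a noiseless configuration is recovered exactly", {
  cfg <- synthetic_config(
    weeks = 20,
    demand = demand_spec(150, 0),
    cutting = bimodal_model("cutting", normal_spec(1.2, 0), 0.9,
                            normal_spec(30, 0), 0.1),
    analysis = bimodal_model("analysis", normal_spec(9.3, 0), 0.65,
                             normal_spec(27.4, 0), 0.35),
    seed = 6)
  rec <- recovery_suite(cfg)
  expect_equal(rec$demand$est_mean, 150)
  expect_equal(rec$cutting$est_means, c(1.2, 30))
  expect_equal(rec$analysis$est_means, c(9.3, 27.4))
  expect_lt(max(abs(rec$analysis$est_proportions - c(0.65, 0.35))), 0.03)
})
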