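test_that("chi-square GOF reproduces hand-computed statistics", {
  same <- chi_square_gof(c(3, 7, 5), c(3, 7, 5))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  r <- chi_square_gof(c(10, 10), c(5, 15))
  expect_equal(r$chi2, 20 / 3, tolerance = 1e-9)
  expect_equal(r$v, 1L)
  expect_equal(r$p, 0.00982, tolerance = 1e-3)
  expect_error(chi_square_gof(10, 10), "2 cells")
  expect_error(chi_square_gof(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(chi_square_gof(c(1, 2), c(0, 3)), "positive")
})

test_that("chi-square GOF equals a brute-force summation oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(2:8, 1)
    o <- rpois(k, 20)
    e <- runif(k, 5, 40)
    # independent oracle: explicit accumulation loop
    acc <- 0
    for (i in seq_len(k)) acc <- acc + (o[i] - e[i])^2 / e[i]
    r <- chi_square_gof(o, e)
    expect_equal(r$chi2, acc, tolerance = 1e-12)
    expect_equal(r$p, pchisq(acc, k - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("equal-probability binning feeds the GOF sensibly", {
  x <- sample_normal(normal_spec(10, 2), 500, uniform_source(8))
  g <- chi_square_gof_normal(x)
  expect_equal(g$k, 20L)
  expect_equal(sum(g$observed), 500)
  expect_true(all(g$expected >= 5))
  expect_gt(g$p, 0.01)
  expect_error(chi_square_gof_normal(rep(1, 50)), "constant")
})

test_that("normality screening accepts normal and rejects bimodal samples", {
  x <- sample_normal(normal_spec(0, 1), 1e4, uniform_source(21))
  expect_true(normality_check(x, alpha = 0.05)$accepted)
  accepted <- vapply(1:20, function(s) {
    z <- sample_normal(normal_spec(5, 2), 1e4, uniform_source(s))
    normality_check(z, alpha = 0.01)$accepted
  }, logical(1))
  expect_gte(mean(accepted), 0.95)
  y <- sample_service_time(analysis_model(), 1e4, uniform_source(22))
  expect_false(normality_check(y, alpha = 0.05)$accepted)
  expect_error(normality_check(rep(3, 100)), "constant")
  expect_error(normality_check(c(1, 2, 3)), "at least 8")
})

test_that("the paired validation interval decides as the shift dictates", {
  X <- c(5, 7, 9, 11)
  ident <- validation_interval(X, X)
  expect_equal(unname(ident$interval), c(0, 0))
  expect_true(ident$contains_zero)
  # a constant shift far beyond the spread rejects the model
  set.seed(1)
  Y <- rnorm(30, 100, 5)
  shifted <- validation_interval(Y + 1000, Y)
  expect_false(shifted$contains_zero)
  expect_gt(shifted$interval["lo"], 0)
  # matched noisy series validate
  noisy <- validation_interval(Y + rnorm(30, 0, 1), Y)
  expect_true(noisy$valid)
  expect_error(validation_interval(1:3, 1:4), "equal length")
  expect_error(validation_interval(1, 1), "at least 2")
})

test_that("the validation interval narrows as 1/sqrt(nu)", {
  width <- function(nu, seed) {
    set.seed(seed)
    X <- rnorm(nu, 50, 4)
    Y <- X + rnorm(nu, 0, 2)
    v <- validation_interval(X, Y)
    unname(diff(v$interval))
  }
  ratios <- vapply(1:5, function(s) width(50, s) / width(5000, s),
                   numeric(1))
  expect_gt(mean(ratios), 10 / 2)
  expect_lt(mean(ratios), 10 * 2)
})

test_that("exact noncentral-t power matches the stats oracle", {
  for (n in c(10, 18, 29)) {
    oracle <- power.t.test(n = n, delta = 5, sd = 6.001,
                           type = "one.sample")$power
    # the oracle neglects the opposite-tail rejection region (~1e-5)
    expect_equal(power_one_sample_t(n, 5, 6.001), oracle,
                 tolerance = 1e-4)
  }
})

test_that("minimal sample sizes land on the study's 29 and 21", {
  expect_identical(sample_size_one_sample_t(3, 4.30), 29L)
  expect_identical(sample_size_one_sample_t(5, 6.001), 21L)
})

test_that("sample size is tight and monotone in the effect size", {
  n <- sample_size_one_sample_t(3, 4.30)
  expect_gte(power_one_sample_t(n, 3, 4.30), 0.95)
  expect_lt(power_one_sample_t(n - 1, 3, 4.30), 0.95)
  deltas <- c(1, 2, 4, 8)
  ns <- vapply(deltas, sample_size_one_sample_t, integer(1), sd = 4.30)
  expect_true(all(diff(ns) <= 0))
  expect_error(sample_size_one_sample_t(-1, 2), "delta")
  expect_error(sample_size_one_sample_t(1e-6, 1e6, n_max = 100),
               "unreachable")
})
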