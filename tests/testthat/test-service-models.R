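test_that("mixture moments follow the closed form", {
  # weight-averaged means frozen from sum(w_i * mu_i)
  expect_equal(mixture_moments(analysis_model())$mean, 15.63953,
               tolerance = 1e-6)
  expect_equal(mixture_moments(cutting_model())$mean, 3.781077,
               tolerance = 1e-6)
  # degenerate mixture: all weight on component 1
  m <- bimodal_model("deg", normal_spec(5, 2), 1, normal_spec(9, 1), 0)
  mm <- mixture_moments(m)
  expect_equal(mm$mean, 5)
  expect_equal(mm$variance, 4)
})

test_that("model construction enforces weights and component order", {
  expect_error(bimodal_model("x", normal_spec(1, 1), 0.6,
                             normal_spec(2, 1), 0.6), "sum to 1")
  expect_error(bimodal_model("x", normal_spec(5, 1), 0.5,
                             normal_spec(2, 1), 0.5), "smaller mean")
})

test_that("service-time sampling matches the mixture law", {
  n <- 1e5
  src <- uniform_source(11)
  x <- sample_service_time(cutting_model(), n, src)
  expect_true(all(x > 0))
  # 3-standard-error band around the mixture mean (truncation bias for
  # the cutting parameters is an order of magnitude below this band)
  mm <- mixture_moments(cutting_model())
  expect_lt(abs(mean(x) - mm$mean), 3 * sqrt(mm$variance / n))
  y <- sample_service_time(analysis_model(), n, uniform_source(12))
  expect_lt(abs(mean(y) - mixture_moments(analysis_model())$mean), 0.15)
  # realized component identity tracks the weights
  frac1 <- mean(attr(y, "component") == 1L)
  expect_lt(abs(frac1 - 0.648), 0.01)
  z <- sample_service_time(analysis_model(), 0, src)
  expect_length(z, 0)
})

test_that("threshold classification labels, splits and errors correctly", {
  # all below the low threshold
  all_low <- classify_bimodal(c(1, 2, 3, 10))
  expect_equal(all_low$proportions, c(1, 0))
  # the study's 54-case split: 35 short vs 19 long analyses
  x54 <- c(seq(2, 15, length.out = 35), seq(21, 40, length.out = 19))
  fit <- classify_bimodal(x54)
  expect_equal(fit$counts, c(35L, 19L))
  expect_equal(fit$proportions, c(35, 19) / 54, tolerance = 1e-12)
  expect_equal(round(fit$proportions, 3), c(0.648, 0.352))
  # in-gap values go to the nearer threshold, ties to group 1
  gap <- classify_bimodal(c(5, 25, 17, 19, 18))
  expect_equal(gap$labels, c(1L, 2L, 1L, 2L, 1L))
  # everything inside the gap is unclassifiable
  expect_error(classify_bimodal(c(17, 18, 19)), "outside")
  expect_error(classify_bimodal(5), "at least two")
})

test_that("classification is idempotent and permutation-invariant", {
  x <- sample_service_time(analysis_model(), 500, uniform_source(4))
  fit <- classify_bimodal(x)
  perm <- sample(length(x))
  fit_p <- classify_bimodal(x[perm])
  expect_equal(fit_p$labels, fit$labels[perm])
  expect_equal(sort(fit_p$proportions), sort(fit$proportions))
  # re-classifying either group alone returns it unchanged
  g1 <- x[fit$labels == 1L]
  expect_true(all(classify_bimodal(g1)$labels == 1L))
})

test_that("sampling then classifying recovers the generating parameters", {
  # analysis model: thresholds cut cleanly between the modes, so the
  # recovered parameters land on the generating ones
  x <- sample_service_time(analysis_model(), 5000, uniform_source(1))
  fit <- classify_bimodal(x)
  expect_lt(abs(fit$specs[[1]]$mu - 9.2571), 0.5)
  expect_lt(abs(fit$specs[[2]]$mu - 27.389), 0.5)
  expect_lt(max(abs(fit$proportions - c(0.648, 0.352))), 0.05)
})

test_that("recovered group means match the region-conditional expectations", {
  # independent oracle: with group regions (0, 18) and (18, Inf) under
  # the nearer-threshold rule, the expected group mean is the mixture of
  # per-component doubly-truncated normal means. The wide slow cutting
  # mode (SD 10) is inherently over-estimated by threshold splitting;
  # the oracle quantifies exactly by how much.
  region_stats <- function(model, lo, hi) {
    comp <- model$components
    mass <- mu_r <- numeric(2)
    for (k in 1:2) {
      mu <- comp[[k]]$spec$mu; s <- comp[[k]]$spec$sigma
      a <- (max(lo, 0) - mu) / s; b <- (hi - mu) / s
      pos <- 1 - pnorm(-mu / s) # positive-support renormalization
      p_ab <- pnorm(b) - pnorm(a)
      mass[k] <- comp[[k]]$weight * p_ab / pos
      mu_r[k] <- if (p_ab > 0) mu + s * (dnorm(a) - dnorm(b)) / p_ab else 0
    }
    c(mass = sum(mass), mean = sum(mass * mu_r) / sum(mass))
  }
  n <- 5000
  for (model in list(cutting_model(), analysis_model())) {
    x <- sample_service_time(model, n, uniform_source(1))
    fit <- classify_bimodal(x)
    g1 <- region_stats(model, 0, 18)
    g2 <- region_stats(model, 18, Inf)
    expect_lt(abs(fit$proportions[1] - g1["mass"]), 0.03)
    for (g in list(list(g1, 1L), list(g2, 2L))) {
      ex <- g[[1]]; k <- g[[2]]
      n_g <- fit$counts[k]
      se <- fit$specs[[k]]$sigma / sqrt(n_g)
      expect_lt(abs(fit$specs[[k]]$mu - ex["mean"]), 4 * se + 0.05)
    }
  }
})

test_that("independent-mixture combination weights multiply the marginals", {
  w <- combination_weights()
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(unname(w["C1A1"]), 0.909 * 0.648, tolerance = 1e-12)
})
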