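#' Chi-square goodness-of-fit test from observed and expected counts
#'
#' Computes `chi2 = sum((o - e)^2 / e)` over the `k` cells, with
#' `v = k - 1` degrees of freedom and the p-value from the chi-square
#' survival function.
#'
#' @param observed,expected Numeric vectors of equal length >= 2;
#'   expected counts must all be positive.
#' @return An object of class `gof_result`: list with `chi2`, `k`, `v`,
#'   `p`, `observed`, `expected`.
#' @examples
#' chi_square_gof(c(10, 10), c(5, 15))
#' @export
chi_square_gof <- function(observed, expected) {
  if (!is.numeric(observed) || !is.numeric(expected) ||
      length(observed) != length(expected)) {
    stop("`observed` and `expected` must be numeric vectors of equal length",
         call. = FALSE)
  }
  k <- length(observed)
  if (k < 2L) stop("need at least 2 cells", call. = FALSE)
  if (any(expected <= 0)) {
    stop("all expected counts must be positive", call. = FALSE)
  }
  chi2 <- sum((observed - expected)^2 / expected)
  v <- k - 1L
  structure(list(chi2 = chi2, k = k, v = v,
                 p = stats::pchisq(chi2, df = v, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result> chi2 = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$v, x$p))
  invisible(x)
}

#' Chi-square goodness of fit of a sample to the normal distribution
#'
#' Bins the sample into equal-probability cells of a normal with the
#' sample mean and SD (so every expected count is `n / k >= 5`), with
#' `k = max(2, min(20, floor(n / 5)))` cells, and applies
#' [chi_square_gof()].
#'
#' @param samples Numeric vector, `n >= 10`.
#' @return A `gof_result`.
#' @export
chi_square_gof_normal <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 10L) {
    stop("need at least 10 samples", call. = FALSE)
  }
  n <- length(samples)
  if (stats::sd(samples) == 0) {
    stop("sample is constant: normal fit is degenerate", call. = FALSE)
  }
  k <- max(2L, min(20L, floor(n / 5)))
  breaks <- stats::qnorm(seq(0, 1, length.out = k + 1L),
                         mean = mean(samples), sd = stats::sd(samples))
  breaks[1] <- -Inf
  breaks[k + 1L] <- Inf
  observed <- as.numeric(table(cut(samples, breaks = breaks)))
  chi_square_gof(observed, rep(n / k, k))
}

#' Anderson-Darling normality screen
#'
#' Tests the sample against a normal distribution with estimated
#' parameters. The sample is "accepted" as normal when the p-value
#' exceeds `alpha`. A constant sample is rejected up front with an
#' error, since the normal fit is degenerate.
#'
#' @param samples Numeric vector, `n >= 8`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `normality_result`: list with `A2`
#'   (the Anderson-Darling statistic), `p`, `accepted`, `alpha`, `n`.
#' @export
normality_check <- function(samples, alpha = 0.05) {
  if (!is.numeric(samples) || length(samples) < 8L) {
    stop("Anderson-Darling check needs at least 8 samples", call. = FALSE)
  }
  if (stats::sd(samples) == 0) {
    stop("sample is constant: normality is not assessable", call. = FALSE)
  }
  fit <- nortest::ad.test(samples)
  structure(list(A2 = unname(fit$statistic), p = fit$p.value,
                 accepted = fit$p.value > alpha, alpha = alpha,
                 n = length(samples)),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("<normality_result> A2 = %.4f, p = %.4g, %s at alpha = %g\n",
              x$A2, x$p, if (x$accepted) "accepted" else "rejected", x$alpha))
  invisible(x)
}

#' Paired model-validation interval
#'
#' Compares a real-system series `X` with a simulated series `Y` paired
#' by period. The interval is
#' `(Xbar - Ybar) -/+ t(v - 1, 1 - alpha) * sqrt(var(X - Y) / v)` with
#' `v` the number of pairs; the simulation model is considered valid
#' when the interval contains zero (no evidence of a systematic
#' difference between system and model).
#'
#' @param X,Y Numeric vectors of equal length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `validation_result`: list with `X_bar`,
#'   `Y_bar`, `var_diff`, `t_quantile`, `interval` (lo, hi),
#'   `contains_zero`, `valid`, `nu`.
#' @export
validation_interval <- function(X, Y, alpha = 0.05) {
  if (!is.numeric(X) || !is.numeric(Y) || length(X) != length(Y)) {
    stop("`X` and `Y` must be numeric vectors of equal length", call. = FALSE)
  }
  nu <- length(X)
  if (nu < 2L) stop("need at least 2 paired periods", call. = FALSE)
  d <- X - Y
  var_diff <- stats::var(d) / nu
  tq <- stats::qt(1 - alpha, df = nu - 1L)
  ctr <- mean(X) - mean(Y)
  half <- tq * sqrt(var_diff)
  lo <- ctr - half
  hi <- ctr + half
  structure(list(X_bar = mean(X), Y_bar = mean(Y), var_diff = var_diff,
                 t_quantile = tq, interval = c(lo = lo, hi = hi),
                 contains_zero = lo <= 0 && 0 <= hi,
                 valid = lo <= 0 && 0 <= hi, nu = nu, alpha = alpha),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> interval (%.3f, %.3f): model %s\n",
              x$interval["lo"], x$interval["hi"],
              if (x$valid) "valid (contains zero)" else "rejected"))
  invisible(x)
}

#' Exact power of a two-sided one-sample t-test
#'
#' Uses the noncentral-t distribution with noncentrality
#' `delta / sd * sqrt(n)`, not a normal approximation.
#'
#' @param n Sample size (>= 2).
#' @param delta Detectable mean difference, in minutes.
#' @param sd Standard deviation, in minutes.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power, a probability in (0, 1).
#' @export
power_one_sample_t <- function(n, delta, sd, alpha = 0.05) {
  stopifnot(n >= 2, delta > 0, sd > 0, alpha > 0, alpha < 1)
  ncp <- delta / sd * sqrt(n)
  crit <- stats::qt(1 - alpha / 2, df = n - 1)
  stats::pt(-crit, df = n - 1, ncp = ncp) +
    stats::pt(crit, df = n - 1, ncp = ncp, lower.tail = FALSE)
}

#' Minimal sample size for a two-sided one-sample t-test
#'
#' Iterates `n` upward until the exact noncentral-t power reaches the
#' target.
#'
#' @param delta Detectable mean difference (> 0), minutes.
#' @param sd Standard deviation (> 0), minutes.
#' @param alpha Significance level (default 0.05).
#' @param power Target power in (0, 1) (default 0.95).
#' @param n_max Search cap (default 1e6).
#' @return Smallest integer `n` with power >= `power`.
#' @examples
#' sample_size_one_sample_t(3, 4.30)   # 29
#' sample_size_one_sample_t(5, 6.001)  # 21
#' @export
sample_size_one_sample_t <- function(delta, sd, alpha = 0.05, power = 0.95,
                                     n_max = 1e6) {
  if (!is.numeric(delta) || delta <= 0) stop("`delta` must be > 0", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  if (!is.numeric(power) || power <= 0 || power >= 1) {
    stop("`power` must lie in (0, 1)", call. = FALSE)
  }
  n <- 2L
  while (n <= n_max) {
    if (power_one_sample_t(n, delta, sd, alpha) >= power) return(n)
    n <- n + 1L
  }
  stop("target power unreachable within n <= ", n_max, call. = FALSE)
}
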