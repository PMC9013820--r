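#' Two-component Gaussian mixture service-time model
#'
#' Service times at the cutting and slide-analysis stages of the biopsy
#' workflow are bimodal: a fast routine mode and a slow mode for complex
#' specimens. A `bimodal_model` holds exactly two weighted
#' [normal_spec()] components; weights must sum to one and the first
#' component must have the smaller mean.
#'
#' @param name Label, e.g. `"cutting"` or `"analysis"`.
#' @param spec1,spec2 [normal_spec()] components (spec1 mean < spec2 mean).
#' @param w1,w2 Component weights in `[0, 1]`, summing to 1 (within 1e-9).
#' @return An object of class `bimodal_model`.
#' @seealso [cutting_model()], [analysis_model()], [mixture_moments()],
#'   [sample_service_time()], [classify_bimodal()]
#' @export
bimodal_model <- function(name, spec1, w1, spec2, w2) {
  stopifnot(inherits(spec1, "normal_spec"), inherits(spec2, "normal_spec"))
  if (!is.numeric(w1) || !is.numeric(w2) || w1 < 0 || w2 < 0 ||
      w1 > 1 || w2 > 1) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (abs(w1 + w2 - 1) > 1e-9) {
    stop("component weights must sum to 1", call. = FALSE)
  }
  if (!(spec1$mu < spec2$mu)) {
    stop("component 1 must have the smaller mean", call. = FALSE)
  }
  structure(
    list(name = as.character(name),
         components = list(
           list(spec = spec1, weight = as.numeric(w1)),
           list(spec = spec2, weight = as.numeric(w2)))),
    class = "bimodal_model")
}

#' @export
print.bimodal_model <- function(x, ...) {
  cat(sprintf("<bimodal_model> %s\n", x$name))
  for (i in 1:2) {
    c_i <- x$components[[i]]
    cat(sprintf("  component %d: N(%.4f, %.4f) min, weight %.3f\n",
                i, c_i$spec$mu, c_i$spec$sigma, c_i$weight))
  }
  invisible(x)
}

#' Default specimen-cutting service-time model
#'
#' Routine cuts average 1.1563 min (SD 0.423) and make up 90.9 percent of
#' cases; cuts of large organ sections average 30 min (SD 10) and make up
#' the remaining 9.1 percent.
#'
#' @return A [bimodal_model()].
#' @export
cutting_model <- function() {
  bimodal_model("cutting",
                normal_spec(1.1563, 0.423), 0.909,
                normal_spec(30, 10), 0.091)
}

#' Default slide-analysis service-time model
#'
#' Routine diagnoses average 9.2571 min (SD 4.3069) at 64.8 percent of
#' cases; complex diagnoses average 27.389 min (SD 6.001) at 35.2 percent.
#'
#' @return A [bimodal_model()].
#' @export
analysis_model <- function() {
  bimodal_model("analysis",
                normal_spec(9.2571, 4.3069), 0.648,
                normal_spec(27.389, 6.001), 0.352)
}

#' Closed-form mean and variance of a bimodal service-time model
#'
#' The mixture mean is the weight-averaged component mean; the variance
#' follows the standard mixture decomposition
#' `sum(w * (sigma^2 + mu^2)) - mean^2`.
#'
#' @param model A [bimodal_model()].
#' @return List with elements `mean` (minutes) and `variance` (minutes^2).
#' @examples
#' mixture_moments(analysis_model())$mean # 15.64 min
#' @export
mixture_moments <- function(model) {
  stopifnot(inherits(model, "bimodal_model"))
  w <- vapply(model$components, `[[`, numeric(1), "weight")
  mu <- vapply(model$components, function(c_i) c_i$spec$mu, numeric(1))
  s2 <- vapply(model$components, function(c_i) c_i$spec$sigma^2, numeric(1))
  m <- sum(w * mu)
  list(mean = m, variance = sum(w * (s2 + mu^2)) - m^2)
}

#' Sample service times from a bimodal model
#'
#' Each draw first selects a component by weight (one uniform), then
#' samples a positive-only normal deviate from that component via the
#' Box-Muller transform. The generating component of each draw is
#' recorded in the `"component"` attribute, which lets tests check the
#' realized component proportions against the model weights.
#'
#' @param model A [bimodal_model()].
#' @param n Number of draws (>= 0).
#' @param source A [uniform_source()].
#' @return Numeric vector of minutes with integer attribute `"component"`.
#' @export
sample_service_time <- function(model, n, source) {
  stopifnot(inherits(model, "bimodal_model"), inherits(source, "uniform_source"))
  if (!is.numeric(n) || length(n) != 1L || n < 0) {
    stop("`n` must be a single non-negative number", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 0L) {
    return(structure(numeric(0), component = integer(0)))
  }
  u <- next_uniform(source, n)
  comp <- ifelse(u < model$components[[1]]$weight, 1L, 2L)
  out <- numeric(n)
  for (k in 1:2) {
    idx <- which(comp == k)
    if (length(idx)) {
      out[idx] <- sample_normal(model$components[[k]]$spec, length(idx),
                                source, positive_only = TRUE)
    }
  }
  structure(out, component = comp)
}

#' Bimodal classification rule
#'
#' Values below `low_threshold` belong to group 1 and values above
#' `high_threshold` to group 2; values falling inside the gap are
#' assigned to the group of the nearer threshold (ties to group 1).
#' The defaults of 16 and 20 minutes are the thresholds that separate
#' routine from complex slide analyses in the biopsy workflow.
#'
#' @param low_threshold,high_threshold Minutes, with `low <= high`.
#' @return An object of class `classification_rule`.
#' @export
classification_rule <- function(low_threshold = 16, high_threshold = 20) {
  if (!is.numeric(low_threshold) || !is.numeric(high_threshold) ||
      low_threshold > high_threshold) {
    stop("need numeric thresholds with low <= high", call. = FALSE)
  }
  structure(list(low_threshold = as.numeric(low_threshold),
                 high_threshold = as.numeric(high_threshold)),
            class = "classification_rule")
}

#' Split duration samples into the two service-time groups
#'
#' Threshold-split recovery of the two-component model: samples are
#' labelled by the rule, and each group is summarized by its empirical
#' mean and standard deviation plus its proportion of the sample. This
#' is deliberately a moment/threshold estimator, not an EM fit: it is
#' the procedure the bimodal service-time models were derived with.
#'
#' @param samples Numeric vector of durations in minutes.
#' @param rule A [classification_rule()].
#' @return An object of class `bimodal_fit`: list with `labels` (1/2 per
#'   sample), `proportions` (length 2), `counts`, and `specs` (a list of
#'   two [normal_spec()] built from the group means/SDs).
#' @examples
#' fit <- classify_bimodal(c(5, 8, 11, 25, 30))
#' fit$proportions
#' @export
classify_bimodal <- function(samples, rule = classification_rule()) {
  stopifnot(inherits(rule, "classification_rule"))
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop("need at least two numeric samples", call. = FALSE)
  }
  lo <- rule$low_threshold
  hi <- rule$high_threshold
  outside <- samples < lo | samples > hi
  if (sum(outside) < 2L) {
    stop("classification needs at least two samples outside the (",
         lo, ", ", hi, ") gap", call. = FALSE)
  }
  labels <- ifelse(samples < lo, 1L,
                   ifelse(samples > hi, 2L,
                          ifelse(samples - lo <= hi - samples, 1L, 2L)))
  counts <- c(sum(labels == 1L), sum(labels == 2L))
  specs <- lapply(1:2, function(k) {
    x <- samples[labels == k]
    if (length(x) == 0L) return(NULL)
    s <- if (length(x) > 1L) stats::sd(x) else 0
    normal_spec(mean(x), s)
  })
  structure(list(labels = labels,
                 proportions = counts / length(samples),
                 counts = counts,
                 specs = specs,
                 rule = rule),
            class = "bimodal_fit")
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat("<bimodal_fit>\n")
  for (k in 1:2) {
    if (is.null(x$specs[[k]])) {
      cat(sprintf("  group %d: empty\n", k))
    } else {
      cat(sprintf("  group %d: n = %d (%.1f%%), mean = %.3f min, sd = %.3f min\n",
                  k, x$counts[k], 100 * x$proportions[k],
                  x$specs[[k]]$mu, x$specs[[k]]$sigma))
    }
  }
  invisible(x)
}

#' Combination weights implied by independent cutting and analysis mixtures
#'
#' If the cutting and analysis group memberships were independent, the
#' share of biopsies in each cut-by-analysis combination would be the
#' product of the marginal weights. The observed combination counts used
#' for capacity planning are not consistent with independence, so this
#' allocation is provided for sensitivity analysis only.
#'
#' @param cutting,analysis [bimodal_model()] objects.
#' @return Named numeric vector over `C1A1`, `C1A2`, `C2A1`, `C2A2`.
#' @export
combination_weights <- function(cutting = cutting_model(),
                                analysis = analysis_model()) {
  wc <- vapply(cutting$components, `[[`, numeric(1), "weight")
  wa <- vapply(analysis$components, `[[`, numeric(1), "weight")
  c(C1A1 = wc[1] * wa[1], C1A2 = wc[1] * wa[2],
    C2A1 = wc[2] * wa[1], C2A2 = wc[2] * wa[2])
}
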