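#' Configuration for the synthetic biopsy-log generator
#'
#' Describes a hospital-like stream of biopsies with the statistical
#' structure the rest of the package assumes: normally distributed
#' weekly arrivals, bimodal cutting and analysis times, a specialty mix
#' in which the top four specialties (gynecology, general surgery,
#' gastroenterology, minor surgery) jointly account for 81.24 percent of
#' requests, an own-hospital/network provenance split of 87/13, and a
#' diagnosis-capacity shortfall that opens a received-vs-diagnosed gap
#' from a given onset week. Within the top-four block the default
#' per-specialty shares decline 4:3:2:1; only the block total is an
#' observed quantity.
#'
#' Diagnosis capacity is unlimited before `backlog_onset_week` and a
#' constant `diagnosis_capacity_per_week` from then on. The default of
#' 28 diagnoses per week is calibrated so that a 43-week run leaves
#' about 38 percent of received biopsies undiagnosed (roughly 2,468 of
#' 6,500).
#'
#' @param weeks Number of weeks to generate (default 52).
#' @param demand A [demand_spec()].
#' @param cutting,analysis [bimodal_model()] service-time models.
#' @param specialty_weights Named probabilities summing to 1.
#' @param provenance_split Named probabilities (`own`, `network`)
#'   summing to 1.
#' @param diagnosis_capacity_per_week Diagnoses per week once the
#'   shortfall starts (>= 0).
#' @param backlog_onset_week First week of constrained capacity.
#' @param seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(weeks = 52L,
                             demand = demand_spec(),
                             cutting = cutting_model(),
                             analysis = analysis_model(),
                             specialty_weights = c(
                               gynecology = 0.8124 * 0.4,
                               general_surgery = 0.8124 * 0.3,
                               gastroenterology = 0.8124 * 0.2,
                               minor_surgery = 0.8124 * 0.1,
                               other = 0.1876),
                             provenance_split = c(own = 0.87, network = 0.13),
                             diagnosis_capacity_per_week = 28,
                             backlog_onset_week = 24L,
                             seed = 1L) {
  stopifnot(inherits(demand, "demand_spec"),
            inherits(cutting, "bimodal_model"),
            inherits(analysis, "bimodal_model"))
  if (abs(sum(specialty_weights) - 1) > 1e-9) {
    stop("`specialty_weights` must sum to 1", call. = FALSE)
  }
  if (abs(sum(provenance_split) - 1) > 1e-9) {
    stop("`provenance_split` must sum to 1", call. = FALSE)
  }
  if (diagnosis_capacity_per_week < 0) {
    stop("`diagnosis_capacity_per_week` must be >= 0", call. = FALSE)
  }
  structure(list(weeks = as.integer(weeks), demand = demand,
                 cutting = cutting, analysis = analysis,
                 specialty_weights = specialty_weights,
                 provenance_split = provenance_split,
                 diagnosis_capacity_per_week = diagnosis_capacity_per_week,
                 backlog_onset_week = as.integer(backlog_onset_week),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Sample categorical labels from named weights using source uniforms.
sample_categorical <- function(weights, n, source) {
  if (n == 0L) return(character(0))
  u <- next_uniform(source, n)
  br <- cumsum(weights) / sum(weights)
  names(weights)[findInterval(u, br) + 1L]
}

#' Generate a synthetic biopsy log
#'
#' Draws weekly arrival counts from the demand normal (rounded half-up,
#' floored at zero), assigns specialty and provenance by the configured
#' weights, samples cutting and analysis durations from the bimodal
#' models (recording the generating component of each), and assigns
#' diagnosis weeks FIFO under the weekly diagnosis capacity: unlimited
#' before the backlog onset week, constant after. Biopsies not
#' diagnosed within the horizon stay pending (`diagnosed_week = NA`).
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame of class `biopsy_log`, one row per biopsy:
#'   `id`, `week`, `specialty`, `provenance`, `cut_group`, `cut_min`,
#'   `analysis_group`, `analysis_min`, `diagnosed_week`. The seed is
#'   attached as attribute `"seed"`.
#' @examples
#' log <- generate_biopsy_log(synthetic_config(weeks = 4, seed = 7))
#' head(log)
#' @export
generate_biopsy_log <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  src <- uniform_source(cfg$seed)
  dspec <- normal_spec(cfg$demand$weekly_mean, cfg$demand$weekly_sd)
  counts <- integer(cfg$weeks)
  for (w in seq_len(cfg$weeks)) {
    z <- if (cfg$demand$weekly_sd > 0) sample_normal(dspec, 1L, src)
         else cfg$demand$weekly_mean
    counts[w] <- round_count(z)
  }
  n <- sum(counts)
  week <- rep(seq_len(cfg$weeks), counts)
  specialty <- sample_categorical(cfg$specialty_weights, n, src)
  provenance <- sample_categorical(cfg$provenance_split, n, src)
  cut_min <- sample_service_time(cfg$cutting, n, src)
  analysis_min <- sample_service_time(cfg$analysis, n, src)
  log <- data.frame(
    id = seq_len(n), week = week,
    specialty = specialty, provenance = provenance,
    cut_group = attr(cut_min, "component"),
    cut_min = as.numeric(cut_min),
    analysis_group = attr(analysis_min, "component"),
    analysis_min = as.numeric(analysis_min),
    diagnosed_week = rep(NA_integer_, n),
    stringsAsFactors = FALSE)
  # FIFO diagnosis under weekly capacity
  pending <- integer(0)
  for (w in seq_len(cfg$weeks)) {
    pending <- c(pending, which(week == w))
    cap <- if (w < cfg$backlog_onset_week) length(pending)
           else min(length(pending), cfg$diagnosis_capacity_per_week)
    if (cap > 0L) {
      served <- pending[seq_len(cap)]
      log$diagnosed_week[served] <- w
      pending <- pending[-seq_len(cap)]
    }
  }
  structure(log, seed = cfg$seed, class = c("biopsy_log", "data.frame"))
}

#' Cumulative received and diagnosed series
#'
#' Per-week cumulative counts of biopsies received and diagnosed, and
#' their gap (the backlog at the end of each week).
#'
#' @param log A [generate_biopsy_log()] result.
#' @return Data frame with `week`, `received_cum`, `diagnosed_cum`,
#'   `gap` (empty for an empty log).
#' @export
gap_series <- function(log) {
  stopifnot(is.data.frame(log))
  if (nrow(log) == 0L) {
    return(data.frame(week = integer(0), received_cum = numeric(0),
                      diagnosed_cum = numeric(0), gap = numeric(0)))
  }
  weeks <- seq_len(max(log$week))
  rec <- cumsum(tabulate(log$week, nbins = length(weeks)))
  diag_w <- log$diagnosed_week[!is.na(log$diagnosed_week)]
  dia <- cumsum(tabulate(diag_w, nbins = length(weeks)))
  data.frame(week = weeks, received_cum = rec, diagnosed_cum = dia,
             gap = rec - dia)
}

#' Estimator-vs-generator recovery report
#'
#' Closes the loop between the synthetic generator and the inference
#' toolkit: generates a log under `cfg` and re-estimates the quantities
#' the generator was parameterized with — the weekly demand mean/SD
#' (with an Anderson-Darling normality screen and a chi-square
#' goodness-of-fit check of the weekly counts), and the mixture
#' proportions and component means of the cutting and analysis models
#' via [classify_bimodal()].
#'
#' @param cfg A [synthetic_config()].
#' @return An object of class `recovery_report`: list with the
#'   generated `log` size, a `demand` block (truth vs estimate, AD and
#'   chi-square results), and `cutting` / `analysis` blocks (generating
#'   vs recovered proportions and means).
#' @export
recovery_suite <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  log <- generate_biopsy_log(cfg)
  counts <- tabulate(log$week, nbins = cfg$weeks)
  demand_block <- list(
    true_mean = cfg$demand$weekly_mean,
    true_sd = cfg$demand$weekly_sd,
    est_mean = mean(counts),
    est_sd = stats::sd(counts),
    normality = if (stats::sd(counts) > 0) normality_check(counts) else NULL,
    gof = if (stats::sd(counts) > 0 && length(counts) >= 10L) {
      chi_square_gof_normal(counts)
    } else NULL)
  recover_model <- function(model, x) {
    fit <- classify_bimodal(x, classification_rule())
    list(true_weights = vapply(model$components, `[[`, numeric(1), "weight"),
         est_proportions = fit$proportions,
         true_means = vapply(model$components,
                             function(c_i) c_i$spec$mu, numeric(1)),
         est_means = vapply(fit$specs, function(s) {
           if (is.null(s)) NA_real_ else s$mu
         }, numeric(1)))
  }
  structure(list(n = nrow(log), weeks = cfg$weeks, seed = cfg$seed,
                 demand = demand_block,
                 cutting = recover_model(cfg$cutting, log$cut_min),
                 analysis = recover_model(cfg$analysis, log$analysis_min)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d biopsies over %d weeks (seed %d)\n",
              x$n, x$weeks, x$seed))
  cat(sprintf("  demand mean: true %.2f, est %.2f; sd: true %.2f, est %.2f\n",
              x$demand$true_mean, x$demand$est_mean,
              x$demand$true_sd, x$demand$est_sd))
  for (nm in c("cutting", "analysis")) {
    b <- x[[nm]]
    cat(sprintf("  %s: proportions %.3f/%.3f (true %.3f/%.3f), means %.2f/%.2f (true %.2f/%.2f)\n",
                nm, b$est_proportions[1], b$est_proportions[2],
                b$true_weights[1], b$true_weights[2],
                b$est_means[1], b$est_means[2],
                b$true_means[1], b$true_means[2]))
  }
  invisible(x)
}
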