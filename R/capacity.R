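#' Annual biopsy counts by cutting/analysis combination
#'
#' The observed annual allocation of biopsies over the four combinations
#' of cutting group (routine C1 / large-section C2) and analysis group
#' (routine A1 / complex A2) used for capacity planning.
#'
#' @return Named integer vector `C1A1`, `C1A2`, `C2A1`, `C2A2`
#'   (6748, 1242, 210, 112; total 8312).
#' @export
pathology_combination_counts <- function() {
  c(C1A1 = 6748L, C1A2 = 1242L, C2A1 = 210L, C2A2 = 112L)
}

#' Simulate pathologist hours for one cutting/analysis combination
#'
#' Per replicate, draws `count` positive-only cutting times and `count`
#' positive-only analysis times from the given normal components via the
#' Box-Muller transform, sums each, and converts to hours; reports the
#' mean over replicates.
#'
#' @param count Number of biopsies in the combination (>= 0).
#' @param cut,analysis [normal_spec()] service-time components, minutes.
#' @param replicates Number of replicates (>= 1, default 10).
#' @param source A [uniform_source()].
#' @return List with `cut_hours`, `analysis_hours`, `total_hours`.
#' @export
simulate_combination_hours <- function(count, cut, analysis,
                                       replicates = 10L, source) {
  stopifnot(inherits(cut, "normal_spec"), inherits(analysis, "normal_spec"),
            inherits(source, "uniform_source"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  count <- as.integer(count)
  if (count < 0L) stop("`count` must be >= 0", call. = FALSE)
  if (count == 0L) {
    return(list(cut_hours = 0, analysis_hours = 0, total_hours = 0))
  }
  ch <- ah <- numeric(replicates)
  for (r in seq_len(replicates)) {
    ch[r] <- sum(sample_normal(cut, count, source, positive_only = TRUE)) / 60
    ah[r] <- sum(sample_normal(analysis, count, source,
                               positive_only = TRUE)) / 60
  }
  list(cut_hours = mean(ch), analysis_hours = mean(ah),
       total_hours = mean(ch + ah))
}

#' Installed-productive-capacity report over the four combinations
#'
#' Simulates pathologist hours for each cutting/analysis combination and
#' assembles the capacity table: per-combination cutting, analysis, and
#' total hours, with row and grand totals.
#'
#' @param counts Named numeric vector of combination counts, in the
#'   order C1A1, C1A2, C2A1, C2A2 (default
#'   [pathology_combination_counts()]).
#' @param cutting,analysis [bimodal_model()] service-time models; group
#'   1/2 components supply the C1/C2 and A1/A2 times.
#' @param replicates Replicates per combination (default 10).
#' @param seed Integer seed.
#' @return An object of class `capacity_report`: `table` (data frame
#'   with one row per combination plus a Total row of cutting, analysis
#'   and total hours), `grand_total_hours`, `replicates`, `seed`.
#' @examples
#' rep <- capacity_report(replicates = 2, seed = 1)
#' rep$grand_total_hours
#' @export
capacity_report <- function(counts = pathology_combination_counts(),
                            cutting = cutting_model(),
                            analysis = analysis_model(),
                            replicates = 10L, seed = 1L) {
  stopifnot(inherits(cutting, "bimodal_model"),
            inherits(analysis, "bimodal_model"))
  if (length(counts) != 4L) {
    stop("`counts` must give the four combination counts", call. = FALSE)
  }
  if (is.null(names(counts))) {
    names(counts) <- c("C1A1", "C1A2", "C2A1", "C2A2")
  }
  src <- uniform_source(seed)
  combos <- list(C1A1 = c(1L, 1L), C1A2 = c(1L, 2L),
                 C2A1 = c(2L, 1L), C2A2 = c(2L, 2L))
  rows <- lapply(names(combos), function(nm) {
    grp <- combos[[nm]]
    sim <- simulate_combination_hours(
      counts[[nm]],
      cut = cutting$components[[grp[1]]]$spec,
      analysis = analysis$components[[grp[2]]]$spec,
      replicates = replicates, source = src)
    data.frame(combination = nm, count = as.numeric(counts[[nm]]),
               cut_hours = sim$cut_hours,
               analysis_hours = sim$analysis_hours,
               total_hours = sim$total_hours, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  total <- data.frame(combination = "Total", count = sum(tab$count),
                      cut_hours = sum(tab$cut_hours),
                      analysis_hours = sum(tab$analysis_hours),
                      total_hours = sum(tab$total_hours),
                      stringsAsFactors = FALSE)
  structure(list(table = rbind(tab, total),
                 grand_total_hours = total$total_hours,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "capacity_report")
}

#' @export
print.capacity_report <- function(x, ...) {
  cat(sprintf("<capacity_report> %d replicates, seed %d\n",
              x$replicates, x$seed))
  tab <- x$table
  tab[, 3:5] <- round(tab[, 3:5], 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Full-time-equivalent pathologists required for a workload
#'
#' @param total_hours Annual workload in hours (> 0).
#' @param annual_hours_per_fte Productive hours per FTE-year
#'   (default 1776).
#' @return FTE requirement, rounded to 2 decimals.
#' @examples
#' required_fte(2012.78) # 1.13
#' @export
required_fte <- function(total_hours, annual_hours_per_fte = 1776) {
  if (!is.numeric(annual_hours_per_fte) || annual_hours_per_fte <= 0) {
    stop("`annual_hours_per_fte` must be > 0", call. = FALSE)
  }
  if (!is.numeric(total_hours) || any(total_hours < 0)) {
    stop("`total_hours` must be >= 0", call. = FALSE)
  }
  round(total_hours / annual_hours_per_fte, 2)
}

#' Hours of capacity relative to demand at a staffing level
#'
#' Positive values are surplus capacity, negative values a shortfall.
#'
#' @param fte Staffing level in FTE (>= 0).
#' @param required_hours Annual workload in hours.
#' @param annual_hours_per_fte Productive hours per FTE-year
#'   (default 1776).
#' @return `fte * annual_hours_per_fte - required_hours`, in hours.
#' @examples
#' hours_relative_to_demand(0.75, 2012.78) # -680.78
#' @export
hours_relative_to_demand <- function(fte, required_hours,
                                     annual_hours_per_fte = 1776) {
  if (!is.numeric(fte) || any(fte < 0)) {
    stop("`fte` must be >= 0", call. = FALSE)
  }
  fte * annual_hours_per_fte - required_hours
}

#' Staffing report at several FTE levels
#'
#' @param required_hours Annual workload in hours (> 0).
#' @param fte_levels FTE levels to tabulate (default the required level
#'   plus the 0.75 current and 1.75 proposed staffing).
#' @param annual_hours_per_fte Productive hours per FTE-year
#'   (default 1776).
#' @return Data frame with `fte`, `equivalent_hours`, and
#'   `hours_relative_to_demand` per level.
#' @export
staffing_report <- function(required_hours,
                            fte_levels = NULL,
                            annual_hours_per_fte = 1776) {
  req <- required_fte(required_hours, annual_hours_per_fte)
  if (is.null(fte_levels)) fte_levels <- c(req, 0.75, 1.75)
  data.frame(
    fte = fte_levels,
    equivalent_hours = round(fte_levels * annual_hours_per_fte, 0),
    hours_relative_to_demand = round(
      hours_relative_to_demand(fte_levels, required_hours,
                               annual_hours_per_fte), 2))
}

#' Simulated annual biopsy demand
#'
#' Mean over replicates of the sum of weekly integer demand draws
#' (rounded half-up, floored at zero).
#'
#' @param demand A [demand_spec()].
#' @param weeks Working weeks per year (default 50).
#' @param replicates Number of replicates (default 100).
#' @param seed Integer seed.
#' @return Mean annual biopsies (real).
#' @export
simulate_annual_demand <- function(demand = demand_spec(), weeks = 50L,
                                   replicates = 100L, seed = 1L) {
  stopifnot(inherits(demand, "demand_spec"))
  weeks <- as.integer(weeks)
  if (weeks < 0L) stop("`weeks` must be >= 0", call. = FALSE)
  if (weeks == 0L) return(0)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  src <- uniform_source(seed)
  spec <- normal_spec(demand$weekly_mean, demand$weekly_sd)
  totals <- vapply(seq_len(replicates), function(r) {
    draws <- if (demand$weekly_sd > 0) {
      sample_normal(spec, weeks, src)
    } else rep(demand$weekly_mean, weeks)
    sum(round_count(draws))
  }, numeric(1))
  mean(totals)
}
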