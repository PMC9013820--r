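#' Staffing / output scenario
#'
#' A what-if plan for the pathology service: annual fixed staffing cost,
#' optional overtime (given as hours at a rate, or directly as a cost),
#' the annual biopsy output the plan achieves, the resulting diagnosis
#' turnaround in days, and bookkeeping for the backlog of undiagnosed
#' biopsies. The default overtime rate of 7.603 US$/h is derived from a
#' 320-hour overtime block costed at 2,433.03 US$ and can be overridden.
#'
#' @param name Scenario label.
#' @param fixed_cost Annual fixed staffing cost, US$ (>= 0).
#' @param annual_output Annual biopsies produced (> 0).
#' @param diagnosis_days Diagnosis turnaround under the plan, days.
#' @param overtime_hours Overtime hours per year (default 0).
#' @param overtime_rate US$ per overtime hour (default 2433.03 / 320).
#' @param overtime_cost Direct overtime cost, US$; overrides
#'   `overtime_hours * overtime_rate` when given.
#' @param adjustment_months Months to normalize operations, or `NA`.
#' @param backlog_units Backlog of undiagnosed biopsies (default 0).
#' @param pathologist_fte Staffing level in FTE (optional, `NA` allowed).
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, fixed_cost, annual_output, diagnosis_days,
                     overtime_hours = 0, overtime_rate = 2433.03 / 320,
                     overtime_cost = NULL, adjustment_months = NA_real_,
                     backlog_units = 0, pathologist_fte = NA_real_) {
  if (!is.numeric(fixed_cost) || fixed_cost < 0) {
    stop("`fixed_cost` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(annual_output) || annual_output <= 0) {
    stop("`annual_output` must be > 0", call. = FALSE)
  }
  if (overtime_hours < 0 || overtime_rate < 0) {
    stop("overtime terms must be >= 0", call. = FALSE)
  }
  if (is.null(overtime_cost)) {
    overtime_cost <- overtime_hours * overtime_rate
  }
  if (overtime_cost < 0) stop("`overtime_cost` must be >= 0", call. = FALSE)
  structure(list(name = as.character(name),
                 fixed_cost = as.numeric(fixed_cost),
                 overtime_hours = as.numeric(overtime_hours),
                 overtime_rate = as.numeric(overtime_rate),
                 overtime_cost = as.numeric(overtime_cost),
                 annual_output = as.numeric(annual_output),
                 diagnosis_days = as.numeric(diagnosis_days),
                 adjustment_months = as.numeric(adjustment_months),
                 backlog_units = as.numeric(backlog_units),
                 pathologist_fte = as.numeric(pathologist_fte)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: fixed %.2f + overtime %.2f US$, %g biopsies/yr, %g d\n",
              x$name, x$fixed_cost, x$overtime_cost, x$annual_output,
              x$diagnosis_days))
  invisible(x)
}

#' The four reference output-plan scenarios
#'
#' The current single-0.75-FTE operation with heavy overtime, and the
#' three two-pathologist proposals: plain (1), backlog-clearing over 7
#' months by suspending autopsies (2), and backlog-clearing in 3 months
#' with a 320-hour overtime block (3).
#'
#' @return Named list of four [scenario()] objects.
#' @export
default_scenarios <- function() {
  list(
    proposal_1 = scenario("proposal 1", fixed_cost = 46225.00,
                          annual_output = 8300, diagnosis_days = 3,
                          pathologist_fte = 2),
    proposal_2 = scenario("proposal 2", fixed_cost = 46225.00,
                          annual_output = 8300, diagnosis_days = 3,
                          adjustment_months = 7, backlog_units = 2468,
                          pathologist_fte = 2),
    proposal_3 = scenario("proposal 3", fixed_cost = 46225.00,
                          annual_output = 8300, diagnosis_days = 3,
                          overtime_hours = 320, adjustment_months = 3,
                          backlog_units = 2468, pathologist_fte = 2),
    current = scenario("current", fixed_cost = 23112.62,
                       annual_output = 4850, diagnosis_days = 120,
                       overtime_cost = 28518.61, pathologist_fte = 0.75))
}

#' Cost report for a scenario
#'
#' Total cost is fixed plus overtime; cost per biopsy is the total
#' divided by annual output. Money is rounded to cents.
#'
#' @param s A [scenario()].
#' @return An object of class `cost_report`: list with
#'   `annual_fixed_cost`, `overtime_cost`, `total_cost`,
#'   `cost_per_biopsy`, `diagnosis_days`, `name`.
#' @examples
#' cost_report(default_scenarios()$proposal_1)$cost_per_biopsy # 5.57
#' @export
cost_report <- function(s) {
  stopifnot(inherits(s, "scenario"))
  fixed <- round(s$fixed_cost, 2)
  overtime <- round(s$overtime_cost, 2)
  total <- round(fixed + overtime, 2)
  structure(list(name = s$name,
                 annual_fixed_cost = fixed,
                 overtime_cost = overtime,
                 total_cost = total,
                 cost_per_biopsy = round(total / s$annual_output, 2),
                 diagnosis_days = s$diagnosis_days),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("<cost_report> %s: total %.2f US$, %.2f US$/biopsy, %g d\n",
              x$name, x$total_cost, x$cost_per_biopsy, x$diagnosis_days))
  invisible(x)
}

#' Months needed to clear a diagnosis backlog
#'
#' Plain arithmetic: backlog divided by the monthly surplus capacity
#' (capacity beyond incoming demand) available for working it down.
#'
#' @param backlog Undiagnosed biopsies (>= 0).
#' @param monthly_surplus Surplus diagnoses per month (> 0).
#' @return Months (real, not rounded up).
#' @examples
#' backlog_clearance_months(2468, 823) # about 3 months
#' @export
backlog_clearance_months <- function(backlog, monthly_surplus) {
  if (!is.numeric(backlog) || backlog < 0) {
    stop("`backlog` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(monthly_surplus) || monthly_surplus <= 0) {
    stop("backlog never clears: `monthly_surplus` must be > 0",
         call. = FALSE)
  }
  backlog / monthly_surplus
}

#' Compare scenarios
#'
#' Tabulates the cost report of each scenario and ranks by diagnosis
#' days first, then total cost (ties keep input order).
#'
#' @param scenarios List of at least two [scenario()] objects.
#' @return Data frame, one row per scenario, sorted by rank.
#' @export
compare_scenarios <- function(scenarios) {
  if (!is.list(scenarios) || length(scenarios) < 2L) {
    stop("need at least two scenarios", call. = FALSE)
  }
  rows <- lapply(scenarios, function(s) {
    cr <- cost_report(s)
    data.frame(name = cr$name,
               annual_fixed_cost = cr$annual_fixed_cost,
               overtime_cost = cr$overtime_cost,
               total_cost = cr$total_cost,
               adjustment_months = s$adjustment_months,
               annual_output = s$annual_output,
               diagnosis_days = cr$diagnosis_days,
               cost_per_biopsy = cr$cost_per_biopsy,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$diagnosis_days, tab$total_cost), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
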