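# The 31 activities of the routine (group-1) biopsy stream with printed
# weekly workload hours at 239 completed units over a 40-hour week.
# Per-unit minutes are back-derived as hours * 60 / 239.
table7_workload <- function() {
  data.frame(
    id = c(3:5, 7:34),
    description = c(
      "Check the biopsy request card data",
      "Number the biopsy consecutively",
      "Enter data into the SIPAT software",
      "Prepare formalin jars for the specimens",
      "Cut the specimens",
      "Enter the data into the SIPAT software",
      "Fix the specimens in formalin jars",
      "Send the specimens to histology",
      "Check the received specimens' information",
      "Centrifuge the jar contents",
      "Clean the embedder",
      "Translate the specimens",
      "Put the specimens in the containers",
      "Pedal-controlled paraffin-filling of the containers",
      "Cool the paraffin wax",
      "Store sample blocks in refrigerator",
      "Clean microtome",
      "Put blade in microtome",
      "Translate the sample blocks to the microtome",
      "Put sample block in microtome",
      "Preliminary trim of the block",
      "Manual slicing",
      "Pass specimens to the bain marie",
      "Place tissue sample on the slide",
      "Number and dry the slide",
      "Place slides in basket",
      "Bring the basket over to the staining area",
      "Staining of the slides in the basket",
      "Storage of the slides",
      "The pathologist goes to the slide storage area",
      "The pathologist examines the slides"),
    category = c(
      "inspection", "operation", "operation", "operation", "operation",
      "operation", "operation", "transport", "inspection", "operation",
      "operation", "transport", "storage", "operation", "operation",
      "storage", "operation", "operation", "transport", "operation",
      "operation", "operation", "operation", "operation", "operation",
      "storage", "transport", "operation", "storage", "transport",
      "operation"),
    hours = c(
      2.336, 5.274, 6.573, 1.460, 4.621, 6.575, 1.997, 1.597, 2.340,
      19.975, 0.399, 1.596, 0.399, 0.799, 0.399, 39.912, 0.399, 0.399,
      1.596, 0.399, 3.021, 8.543, 0.399, 0.399, 19.968, 0.799, 1.595,
      4.488, 37.482, 36.950, 6.569),
    stringsAsFactors = FALSE)
}

#' Reference biopsy-workflow process (routine stream)
#'
#' The 36-activity biopsy diagnosis chain, reconstructed
#' deterministically from the published weekly workload of the routine
#' (group-1) stream: for the 31 activities with a printed weekly-hours
#' figure, the per-unit service time is `hours * 60 / 239` minutes (239
#' completed biopsies per 40-hour week). The five activities with no
#' printed time anywhere (1, 2, 6, 35, 36 — receipt, check-in wait,
#' an idle wait, report preparation, report delivery) carry documented
#' 0.5-minute placeholders and are flagged in the `placeholder` column.
#'
#' This is a synthetic reconstruction, not raw hospital data: the study
#' flowchart's per-activity parameters were never published legibly.
#' Resources follow the department's staffing — a cutting-room
#' technician (reception, data entry, fixation), two histology
#' technicians (block and slide preparation), and one pathologist
#' (specimen cutting, slide diagnosis, report). Transport, storage and
#' queue steps are uncontended delays.
#'
#' @param stochastic If `TRUE`, every activity gets a service-time SD of
#'   20 percent of its mean (for stochastic runs); if `FALSE` (default)
#'   service times are deterministic.
#' @return A [process_definition()] with 36 activities.
#' @examples
#' proc <- fixture_pathology_process()
#' proc
#' @export
fixture_pathology_process <- function(stochastic = FALSE) {
  t7 <- table7_workload()
  t7$mean_min <- t7$hours * 60 / 239
  placeholders <- data.frame(
    id = c(1L, 2L, 6L, 35L, 36L),
    description = c(
      "Receive the tissue specimen",
      "Await check-in of the request",
      "Hold the specimen before cutting",
      "Prepare the diagnosis report",
      "Deliver the report"),
    category = c("operation", "queue", "storage", "operation", "transport"),
    hours = NA_real_,
    mean_min = 0.5,
    stringsAsFactors = FALSE)
  acts <- rbind(t7[, c("id", "description", "category", "hours", "mean_min")],
                placeholders)
  acts <- acts[order(acts$id), ]
  rownames(acts) <- NULL
  acts$sd_min <- if (stochastic) 0.2 * acts$mean_min else 0
  staffed <- list(
    cutting_technician = c(1L, 3L, 4L, 5L, 7L, 9L, 10L),
    histology_technician = c(12L, 13L, 14L, 17L, 18L, 20L, 21L, 23L, 24L,
                             25L, 26L, 27L, 28L, 31L),
    pathologist = c(8L, 34L, 35L))
  acts$resource <- NA_character_
  for (nm in names(staffed)) acts$resource[acts$id %in% staffed[[nm]]] <- nm
  acts$placeholder <- is.na(acts$hours)
  names(acts)[names(acts) == "hours"] <- "table7_hours"
  resources <- data.frame(
    name = c("cutting_technician", "histology_technician", "pathologist"),
    fte = c(1, 2, 1),
    servers = c(1L, 2L, 1L),
    calendar = "weekday",
    annual_hours_per_fte = 1776,
    stringsAsFactors = FALSE)
  calendars <- list(weekday = shift_calendar("07:00-15:00",
                                             days_per_week = 5,
                                             weeks_per_year = 50))
  process_definition(acts, resources, calendars)
}

#' Weekly throughput capacity of a process chain
#'
#' The utilization-based capacity: the number of units per week at which
#' the most loaded single activity reaches 100 percent utilization,
#' `weekly_hours / max(mean_min / servers / 60)`. Every activity is
#' counted as a single station (delays included), matching the
#' utilization accounting used in the workload table the reference
#' process is derived from.
#'
#' @param proc A [process_definition()].
#' @param weekly_hours Operational hours per week (default: the first
#'   calendar's weekly hours).
#' @return Units per week (real).
#' @examples
#' weekly_capacity(fixture_pathology_process()) # about 239.5
#' @export
weekly_capacity <- function(proc, weekly_hours = NULL) {
  stopifnot(inherits(proc, "process_definition"))
  if (is.null(weekly_hours)) {
    weekly_hours <- proc$calendars[[1L]]$weekly_hours
  }
  acts <- proc$activities
  servers <- rep(1, nrow(acts))
  res_idx <- match(acts$resource, proc$resources$name)
  has_res <- !is.na(res_idx)
  servers[has_res] <- proc$resources$servers[res_idx[has_res]]
  per_unit_hours <- acts$mean_min / servers / 60
  weekly_hours / max(per_unit_hours)
}
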