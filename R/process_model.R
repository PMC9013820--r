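#' Activity categories of the biopsy workflow
#'
#' The five classes a workflow activity can belong to: operations,
#' inspections, transport, queue (waiting), and storage.
#'
#' @return Character vector of the five category names.
#' @export
activity_categories <- function() {
  c("operation", "inspection", "transport", "queue", "storage")
}

#' Shift calendar
#'
#' Daily working windows plus working days per week and weeks per year.
#' Windows are `"HH:MM-HH:MM"` strings and must not overlap.
#'
#' @param windows Character vector of daily windows, e.g. `"07:00-15:00"`.
#' @param days_per_week Working days per week (default 5).
#' @param weeks_per_year Working weeks per year (default 50).
#' @return An object of class `shift_calendar` with computed
#'   `daily_hours` and `weekly_hours`.
#' @export
shift_calendar <- function(windows = "07:00-15:00", days_per_week = 5,
                           weeks_per_year = 50) {
  parse_window <- function(w) {
    parts <- strsplit(w, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("bad shift window: ", w, call. = FALSE)
    hm <- function(s) {
      x <- as.numeric(strsplit(trimws(s), ":", fixed = TRUE)[[1]])
      x[1] + x[2] / 60
    }
    c(start = hm(parts[1]), end = hm(parts[2]))
  }
  win <- t(vapply(windows, parse_window, numeric(2)))
  if (any(win[, "end"] <= win[, "start"])) {
    stop("shift windows must end after they start", call. = FALSE)
  }
  ord <- order(win[, "start"])
  win <- win[ord, , drop = FALSE]
  if (nrow(win) > 1L &&
      any(win[-1L, "start"] < win[-nrow(win), "end"])) {
    stop("shift windows must not overlap", call. = FALSE)
  }
  daily <- sum(win[, "end"] - win[, "start"])
  weekly <- daily * days_per_week
  if (weekly <= 0) stop("total weekly hours must be positive", call. = FALSE)
  structure(list(windows = windows, days_per_week = days_per_week,
                 weeks_per_year = weeks_per_year,
                 daily_hours = daily, weekly_hours = weekly),
            class = "shift_calendar")
}

#' @export
print.shift_calendar <- function(x, ...) {
  cat(sprintf("<shift_calendar> %s x %d d/wk (%g h/wk), %d wk/yr\n",
              paste(x$windows, collapse = ", "), x$days_per_week,
              x$weekly_hours, x$weeks_per_year))
  invisible(x)
}

#' Build a validated process definition
#'
#' A process definition is the data model of the biopsy workflow: an
#' ordered table of activities, a table of staffed resources, and shift
#' calendars. Activities form a single chain from specimen receipt to
#' report delivery; each row's `successor` defaults to the next row.
#' Activities without a resource (typically transport, storage and
#' queue steps) are pure delays without contention.
#'
#' @param activities Data frame with columns `id` (unique integers),
#'   `description`, `category` (one of [activity_categories()]),
#'   `mean_min`, `sd_min` (service time, minutes), `resource` (name or
#'   `NA` for a delay); optional `successor` (id or `NA` for the
#'   terminal activity) and `placeholder` (logical).
#' @param resources Data frame with columns `name`, `fte`, `servers`
#'   (parallel servers used by the simulation engine), `calendar`,
#'   `annual_hours_per_fte` (default 1776).
#' @param calendars Named list of [shift_calendar()] objects.
#' @return An object of class `process_definition`.
#' @export
process_definition <- function(activities, resources, calendars) {
  stopifnot(is.data.frame(activities), is.data.frame(resources),
            is.list(calendars))
  activities <- as.data.frame(activities, stringsAsFactors = FALSE)
  resources <- as.data.frame(resources, stringsAsFactors = FALSE)
  need <- c("id", "description", "category", "mean_min", "sd_min", "resource")
  missing_cols <- setdiff(need, names(activities))
  if (length(missing_cols)) {
    stop("activities table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"successor" %in% names(activities)) {
    n <- nrow(activities)
    activities$successor <- c(activities$id[-1L], NA_integer_)
  }
  if (!"placeholder" %in% names(activities)) activities$placeholder <- FALSE
  if (anyDuplicated(activities$id)) {
    stop("activity ids must be unique", call. = FALSE)
  }
  bad_cat <- !(activities$category %in% activity_categories())
  if (any(bad_cat)) {
    stop("unknown category '", activities$category[which(bad_cat)[1]],
         "' for activity id ", activities$id[which(bad_cat)[1]],
         call. = FALSE)
  }
  if (any(activities$mean_min < 0) || any(activities$sd_min < 0)) {
    stop("service-time parameters must be non-negative", call. = FALSE)
  }
  res_names <- resources$name
  if (!"servers" %in% names(resources)) {
    resources$servers <- pmax(1L, as.integer(round(resources$fte)))
  }
  if (!"annual_hours_per_fte" %in% names(resources)) {
    resources$annual_hours_per_fte <- 1776
  }
  used <- stats::na.omit(unique(activities$resource))
  dangling <- setdiff(used, res_names)
  if (length(dangling)) {
    stop("activity references unknown resource: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  bad_cal <- setdiff(resources$calendar, names(calendars))
  if (length(bad_cal)) {
    stop("resource references unknown calendar: ",
         paste(bad_cal, collapse = ", "), call. = FALSE)
  }
  for (cal in calendars) stopifnot(inherits(cal, "shift_calendar"))
  proc <- structure(list(activities = activities, resources = resources,
                         calendars = calendars),
                    class = "process_definition")
  check_chain(proc)
  proc
}

# Walk the successor chain from the first activity; error on cycles,
# dangling successors, or unreachable activities.
check_chain <- function(proc) {
  acts <- proc$activities
  n <- nrow(acts)
  if (n == 0L) stop("process has no activities", call. = FALSE)
  seen <- integer(0)
  cur <- acts$id[1L]
  while (!is.na(cur)) {
    if (cur %in% seen) {
      stop("activity graph contains a cycle through id ", cur, call. = FALSE)
    }
    if (!cur %in% acts$id) {
      stop("successor references unknown activity id ", cur, call. = FALSE)
    }
    seen <- c(seen, cur)
    cur <- acts$successor[match(cur, acts$id)]
  }
  if (length(seen) != n) {
    stop("activity chain does not reach all activities (",
         length(seen), " of ", n, ")", call. = FALSE)
  }
  invisible(TRUE)
}

# Activity ids in chain order.
chain_order <- function(proc) {
  acts <- proc$activities
  out <- integer(0)
  cur <- acts$id[1L]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- acts$successor[match(cur, acts$id)]
  }
  out
}

#' @export
print.process_definition <- function(x, ...) {
  tab <- table(factor(x$activities$category, levels = activity_categories()))
  cat(sprintf("<process_definition> %d activities (%s), %d resources\n",
              nrow(x$activities),
              paste(sprintf("%s %d", names(tab), as.integer(tab)),
                    collapse = ", "),
              nrow(x$resources)))
  invisible(x)
}

#' Remove activities from a process chain
#'
#' Deletes the given activities and re-links the chain around them.
#' The terminal diagnostic activity (the end of the chain) cannot be
#' removed.
#'
#' @param proc A [process_definition()].
#' @param ids Integer ids to remove (may be empty).
#' @return The re-linked `process_definition`.
#' @examples
#' proc <- fixture_pathology_process()
#' nrow(remove_activities(proc, c(6, 32))$activities) # 34
#' @export
remove_activities <- function(proc, ids) {
  stopifnot(inherits(proc, "process_definition"))
  if (length(ids) == 0L) return(proc)
  ids <- as.integer(ids)
  acts <- proc$activities
  unknown <- setdiff(ids, acts$id)
  if (length(unknown)) {
    stop("cannot remove unknown activity id ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ord <- chain_order(proc)
  terminal <- ord[length(ord)]
  if (terminal %in% ids) {
    stop("cannot remove the terminal diagnostic activity (id ",
         terminal, ")", call. = FALSE)
  }
  succ_of <- function(id) acts$successor[match(id, acts$id)]
  for (id in ids) {
    nxt <- succ_of(id)
    while (!is.na(nxt) && nxt %in% ids) nxt <- succ_of(nxt)
    acts$successor[which(acts$successor == id)] <- nxt
  }
  acts <- acts[!acts$id %in% ids, , drop = FALSE]
  rownames(acts) <- NULL
  process_definition(acts, proc$resources, proc$calendars)
}

#' Write a process definition to a config directory
#'
#' Writes `activities.csv` (the activity table) and `resources.yaml`
#' (resources and shift calendars) into `path`.
#'
#' @param proc A [process_definition()].
#' @param path Directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
write_process <- function(proc, path) {
  stopifnot(inherits(proc, "process_definition"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(proc$activities, file.path(path, "activities.csv"),
                   row.names = FALSE)
  res <- lapply(seq_len(nrow(proc$resources)), function(i) {
    as.list(proc$resources[i, , drop = FALSE])
  })
  cal <- lapply(proc$calendars, function(c_i) {
    list(windows = as.list(c_i$windows),
         days_per_week = c_i$days_per_week,
         weeks_per_year = c_i$weeks_per_year)
  })
  yaml::write_yaml(list(calendars = cal, resources = res),
                   file.path(path, "resources.yaml"))
  invisible(path)
}

#' Load a process definition from a config directory
#'
#' Reads `activities.csv` and `resources.yaml` (as written by
#' [write_process()]) and returns a validated [process_definition()].
#'
#' @param path Directory containing the two config files.
#' @return A `process_definition`.
#' @export
load_process <- function(path) {
  acts_file <- file.path(path, "activities.csv")
  res_file <- file.path(path, "resources.yaml")
  if (!file.exists(acts_file) || !file.exists(res_file)) {
    stop("process config needs activities.csv and resources.yaml under ",
         path, call. = FALSE)
  }
  acts <- utils::read.csv(acts_file, stringsAsFactors = FALSE)
  acts$resource <- as.character(acts$resource)
  acts$resource[acts$resource %in% c("", "NA")] <- NA_character_
  cfg <- yaml::read_yaml(res_file)
  calendars <- lapply(cfg$calendars, function(c_i) {
    shift_calendar(unlist(c_i$windows), c_i$days_per_week, c_i$weeks_per_year)
  })
  resources <- do.call(rbind, lapply(cfg$resources, function(r) {
    data.frame(name = r$name, fte = as.numeric(r$fte),
               servers = as.integer(r$servers),
               calendar = r$calendar,
               annual_hours_per_fte = as.numeric(r$annual_hours_per_fte),
               stringsAsFactors = FALSE)
  }))
  process_definition(acts, resources, calendars)
}
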