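#' Weekly demand specification
#'
#' Weekly biopsy arrivals are modelled as a rounded normal count. The
#' defaults are the observed weekly demand of the pathology department:
#' mean 151.55 biopsies, SD 18.45.
#'
#' @param weekly_mean Mean biopsies per week (> 0).
#' @param weekly_sd SD of weekly biopsies (>= 0).
#' @return An object of class `demand_spec`.
#' @export
demand_spec <- function(weekly_mean = 151.55, weekly_sd = 18.45) {
  if (!is.numeric(weekly_mean) || weekly_mean <= 0) {
    stop("`weekly_mean` must be > 0", call. = FALSE)
  }
  if (!is.numeric(weekly_sd) || weekly_sd < 0) {
    stop("`weekly_sd` must be >= 0", call. = FALSE)
  }
  structure(list(weekly_mean = as.numeric(weekly_mean),
                 weekly_sd = as.numeric(weekly_sd)),
            class = "demand_spec")
}

#' @export
print.demand_spec <- function(x, ...) {
  cat(sprintf("<demand_spec> %.2f +/- %.2f biopsies/week\n",
              x$weekly_mean, x$weekly_sd))
  invisible(x)
}

# Round-half-up, floored at zero: the convention for weekly counts.
round_count <- function(x) {
  pmax(0, floor(x + 0.5))
}

#' Run the discrete-event simulation of a biopsy workflow
#'
#' Entities (biopsies) arrive per week — the count drawn from the demand
#' normal (rounded half-up, floored at zero), the arrival instants spread
#' uniformly over the week's operational hours — and traverse the
#' activity chain. Resourced activities queue FIFO on their resource's
#' parallel servers; activities without a resource are uncontended
#' delays. The time axis is operational (on-shift) hours: all resources
#' share the process's shift calendar, so off-shift intervals are
#' excised rather than interleaved. Service times are deterministic when
#' an activity's SD is zero and positive-only Box-Muller normal draws
#' otherwise.
#'
#' With `warmup_hours > 0`, the run is extended by a warm-up phase and
#' all statistics (busy, queue, unit counts, utilization, completions)
#' are accrued only inside the reporting window of `horizon_hours` that
#' follows it, so a congested chain is observed in steady flow rather
#' than while filling. The conservation columns `arrivals_total`,
#' `completions_total`, `in_service`, `in_queue` always cover the whole
#' run.
#'
#' @param proc A [process_definition()].
#' @param demand A [demand_spec()].
#' @param horizon_hours Operational hours of the reporting window (> 0).
#' @param replicates Number of independent replicates (>= 1).
#' @param seed Integer seed; identical inputs give identical results.
#' @param warmup_hours Operational hours simulated before statistics
#'   collection starts (default 0).
#' @param keep_log If `TRUE`, keep the per-service event log.
#' @return An object of class `simulation_result`: `activity` (one row
#'   per replicate x activity with `busy_hours`, `queue_hours`,
#'   `units_in`, `units_out`, `wip`, `utilization`), `summary` (one row
#'   per replicate with windowed arrivals/completions, whole-run totals,
#'   WIP, mean time in system, time-averaged WIP), plus run metadata
#'   (and `event_log` when kept).
#' @examples
#' proc <- fixture_pathology_process()
#' res <- run_simulation(proc, demand_spec(60, 0), horizon_hours = 40,
#'                       replicates = 1, seed = 1)
#' res$summary$completions
#' @export
run_simulation <- function(proc, demand, horizon_hours, replicates = 1L,
                           seed = 1L, warmup_hours = 0, keep_log = FALSE) {
  stopifnot(inherits(proc, "process_definition"),
            inherits(demand, "demand_spec"))
  if (!is.numeric(horizon_hours) || horizon_hours <= 0) {
    stop("`horizon_hours` must be > 0", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)

  ord <- chain_order(proc)
  acts <- proc$activities[match(ord, proc$activities$id), , drop = FALSE]
  n_act <- nrow(acts)
  res_idx <- match(acts$resource, proc$resources$name)
  res_idx[is.na(res_idx)] <- 0L
  servers <- proc$resources$servers
  # configuration check: a staffed activity needs on-shift capacity
  for (i in which(res_idx > 0L)) {
    r <- res_idx[i]
    cal <- proc$calendars[[proc$resources$calendar[r]]]
    if (servers[r] < 1L || cal$weekly_hours <= 0) {
      stop("resource '", proc$resources$name[r],
           "' has no on-shift capacity for activity id ", acts$id[i],
           call. = FALSE)
    }
  }
  if (!is.numeric(warmup_hours) || warmup_hours < 0) {
    stop("`warmup_hours` must be >= 0", call. = FALSE)
  }
  week_min <- proc$calendars[[1L]]$weekly_hours * 60
  W0 <- warmup_hours * 60
  W1 <- W0 + horizon_hours * 60
  src <- uniform_source(seed)

  act_rows <- vector("list", replicates)
  sum_rows <- vector("list", replicates)
  logs <- if (keep_log) vector("list", replicates) else NULL

  for (rep_i in seq_len(replicates)) {
    run <- simulate_replicate(acts, res_idx, servers, demand,
                              week_min, W0, W1, src, keep_log)
    act_rows[[rep_i]] <- data.frame(
      replicate = rep_i, id = acts$id, category = acts$category,
      busy_hours = run$busy_min / 60, queue_hours = run$queue_min / 60,
      units_in = run$units_in, units_out = run$units_out,
      wip = run$units_in - run$units_out,
      utilization = (run$busy_min / 60) / horizon_hours,
      stringsAsFactors = FALSE)
    sum_rows[[rep_i]] <- data.frame(
      replicate = rep_i, arrivals = run$arrivals,
      completions = run$completions,
      arrivals_total = run$arrivals_total,
      completions_total = run$completions_total,
      in_service = run$in_service, in_queue = run$in_queue,
      mean_time_in_system_min = run$mean_tis,
      time_avg_wip = run$area / (W1 - W0),
      stringsAsFactors = FALSE)
    if (keep_log) logs[[rep_i]] <- run$log
  }
  structure(list(activity = do.call(rbind, act_rows),
                 summary = do.call(rbind, sum_rows),
                 horizon_hours = horizon_hours,
                 warmup_hours = warmup_hours,
                 replicates = replicates, seed = as.integer(seed),
                 demand = demand,
                 event_log = if (keep_log) do.call(rbind, logs) else NULL),
            class = "simulation_result")
}

# One replicate of the event loop. Times in operational minutes.
# Statistics are accrued inside the reporting window [W0, W1] only.
simulate_replicate <- function(acts, res_idx, servers, demand,
                               week_min, W0, W1, src, keep_log) {
  overlap <- function(a, b) max(0, min(b, W1) - max(a, W0))
  n_act <- nrow(acts)
  n_res <- max(c(0L, res_idx))
  mean_min <- acts$mean_min
  sd_min <- acts$sd_min

  # precompute arrivals over warm-up plus reporting window
  n_weeks <- ceiling(W1 / week_min)
  arr <- numeric(0)
  for (w in seq_len(n_weeks)) {
    t0 <- (w - 1) * week_min
    t1 <- min(w * week_min, W1)
    if (t0 >= W1) break
    z <- if (demand$weekly_sd > 0) {
      sample_normal(normal_spec(demand$weekly_mean, demand$weekly_sd),
                    1L, src)
    } else demand$weekly_mean
    cnt <- round_count(z)
    if (cnt > 0) arr <- c(arr, t0 + sort(next_uniform(src, cnt)) * (t1 - t0))
  }
  n_arr <- length(arr)

  draw_dur <- function(pos) {
    if (sd_min[pos] > 0) {
      sample_normal(normal_spec(mean_min[pos], sd_min[pos]), 1L, src,
                    positive_only = TRUE)
    } else mean_min[pos]
  }

  busy_min <- numeric(n_act); queue_min <- numeric(n_act)
  units_in <- integer(n_act); units_out <- integer(n_act)
  free <- servers
  rq <- replicate(max(n_res, 1L), list(ent = integer(0), pos = integer(0),
                                       t = numeric(0)), simplify = FALSE)
  # active end-of-service events
  ev_t <- numeric(0); ev_ent <- integer(0); ev_pos <- integer(0)
  arr_time <- arr
  comp_time <- rep(NA_real_, n_arr)
  n_sys <- 0L; area <- 0; t_last <- 0
  log_ent <- integer(0); log_act <- integer(0)
  log_start <- numeric(0); log_end <- numeric(0)

  start_service <- function(ent, pos, t) {
    dur <- draw_dur(pos)
    busy_min[pos] <<- busy_min[pos] + overlap(t, t + dur)
    ev_t <<- c(ev_t, t + dur)
    ev_ent <<- c(ev_ent, ent)
    ev_pos <<- c(ev_pos, pos)
    if (keep_log) {
      log_ent <<- c(log_ent, ent); log_act <<- c(log_act, acts$id[pos])
      log_start <<- c(log_start, t); log_end <<- c(log_end, t + dur)
    }
  }
  enter_activity <- function(ent, pos, t) {
    if (t >= W0 && t <= W1) units_in[pos] <<- units_in[pos] + 1L
    r <- res_idx[pos]
    if (r == 0L) {
      start_service(ent, pos, t)
    } else if (free[r] > 0L) {
      free[r] <<- free[r] - 1L
      start_service(ent, pos, t)
    } else {
      rq[[r]]$ent <<- c(rq[[r]]$ent, ent)
      rq[[r]]$pos <<- c(rq[[r]]$pos, pos)
      rq[[r]]$t <<- c(rq[[r]]$t, t)
    }
  }

  ai <- 1L
  repeat {
    t_arr <- if (ai <= n_arr) arr[ai] else Inf
    t_end <- if (length(ev_t)) min(ev_t) else Inf
    t <- min(t_arr, t_end)
    if (t > W1) break
    if (t_arr <= t_end) {
      area <- area + n_sys * overlap(t_last, t); t_last <- t
      n_sys <- n_sys + 1L
      ent <- ai; ai <- ai + 1L
      enter_activity(ent, 1L, t)
    } else {
      i <- which.min(ev_t)
      ent <- ev_ent[i]; pos <- ev_pos[i]
      ev_t <- ev_t[-i]; ev_ent <- ev_ent[-i]; ev_pos <- ev_pos[-i]
      if (t >= W0 && t <= W1) units_out[pos] <- units_out[pos] + 1L
      r <- res_idx[pos]
      if (r > 0L) {
        if (length(rq[[r]]$ent)) {
          w_ent <- rq[[r]]$ent[1L]; w_pos <- rq[[r]]$pos[1L]
          w_t <- rq[[r]]$t[1L]
          rq[[r]]$ent <- rq[[r]]$ent[-1L]
          rq[[r]]$pos <- rq[[r]]$pos[-1L]
          rq[[r]]$t <- rq[[r]]$t[-1L]
          queue_min[w_pos] <- queue_min[w_pos] + overlap(w_t, t)
          start_service(w_ent, w_pos, t)
        } else {
          free[r] <- free[r] + 1L
        }
      }
      if (pos == n_act) {
        area <- area + n_sys * overlap(t_last, t); t_last <- t
        n_sys <- n_sys - 1L
        comp_time[ent] <- t
      } else {
        enter_activity(ent, pos + 1L, t)
      }
    }
  }
  area <- area + n_sys * overlap(t_last, W1)
  # entities still waiting at the horizon accrue queue time up to H
  in_queue <- 0L
  for (r in seq_len(n_res)) {
    nq <- length(rq[[r]]$ent)
    if (nq) {
      in_queue <- in_queue + nq
      for (j in seq_len(nq)) {
        p <- rq[[r]]$pos[j]
        queue_min[p] <- queue_min[p] + overlap(rq[[r]]$t[j], W1)
      }
    }
  }
  completed <- !is.na(comp_time)
  in_window <- completed & comp_time >= W0 & comp_time <= W1
  list(busy_min = busy_min, queue_min = queue_min,
       units_in = units_in, units_out = units_out,
       arrivals = sum(arr_time >= W0 & arr_time <= W1),
       completions = sum(in_window),
       arrivals_total = n_arr, completions_total = sum(completed),
       in_service = length(ev_t), in_queue = in_queue,
       mean_tis = if (any(in_window)) {
         mean(comp_time[in_window] - arr_time[in_window])
       } else NA_real_,
       area = area,
       log = if (keep_log && length(log_ent)) {
         data.frame(entity = log_ent, activity = log_act,
                    start_min = log_start, end_min = log_end)
       } else if (keep_log) {
         data.frame(entity = integer(0), activity = integer(0),
                    start_min = numeric(0), end_min = numeric(0))
       } else NULL)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d replicate(s) x %g h: %.1f arrivals, %.1f completions\n",
    x$replicates, x$horizon_hours,
    mean(x$summary$arrivals), mean(x$summary$completions)))
  invisible(x)
}

#' Busy hours by activity category
#'
#' Sums busy (held) hours per category across activities, averaged over
#' replicates. All five categories are always reported, with zeros for
#' categories absent from the run.
#'
#' @param result A [run_simulation()] result.
#' @return Named numeric vector over [activity_categories()].
#' @export
category_totals <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  out <- stats::setNames(numeric(5), activity_categories())
  if (nrow(result$activity) == 0L) return(out)
  per_rep <- stats::aggregate(busy_hours ~ category + replicate,
                              data = result$activity, FUN = sum)
  agg <- stats::aggregate(busy_hours ~ category, data = per_rep, FUN = mean)
  out[agg$category] <- agg$busy_hours
  out
}

#' Identify bottleneck activities by utilization
#'
#' Returns the activities whose mean utilization (busy hours divided by
#' the horizon, averaged over replicates) reaches the threshold, sorted
#' by utilization in decreasing order. Utilization here is workload per
#' station, so storage and transport delays can flag as bottlenecks just
#' as staffed operations can.
#'
#' @param result A [run_simulation()] result.
#' @param threshold Utilization cut-off (default 0.90).
#' @return Integer activity ids with a `utilization` attribute.
#' @export
find_bottlenecks <- function(result, threshold = 0.90) {
  stopifnot(inherits(result, "simulation_result"))
  util <- stats::aggregate(utilization ~ id, data = result$activity,
                           FUN = mean)
  util <- util[util$utilization >= threshold & util$utilization > 0, ,
               drop = FALSE]
  util <- util[order(-util$utilization), , drop = FALSE]
  structure(as.integer(util$id), utilization = util$utilization)
}
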