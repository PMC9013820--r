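# Shared fixtures for the suite. Everything is built in code.

# A single-activity process: one resource with `servers` parallel
# servers on a calendar of `weekly_hours`, service mean/sd in minutes.
single_station <- function(mean_min = 1, sd_min = 0, servers = 1L,
                           weekly_hours = 40) {
  acts <- data.frame(id = 1L, description = "station",
                     category = "operation", mean_min = mean_min,
                     sd_min = sd_min, resource = "crew",
                     stringsAsFactors = FALSE)
  res <- data.frame(name = "crew", fte = servers, servers = servers,
                    calendar = "day", annual_hours_per_fte = 1776,
                    stringsAsFactors = FALSE)
  cal <- list(day = shift_calendar(sprintf("07:00-%02d:00",
                                           7 + weekly_hours / 5),
                                   days_per_week = 5))
  process_definition(acts, res, cal)
}

# Closed-form mean of a normal truncated to (0, Inf).
truncated_normal_mean <- function(mu, sigma) {
  if (sigma == 0) return(mu)
  a <- -mu / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}
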