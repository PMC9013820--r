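#' Run manifest
#'
#' Metadata written next to every report so a run can be reproduced:
#' the command, its arguments, the seed, the package version, and a
#' timestamp.
#'
#' @param command Subcommand or function name.
#' @param seed Integer seed of the run.
#' @param args Named list of the remaining arguments.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(command, seed, args = list()) {
  structure(list(command = as.character(command),
                 seed = as.integer(seed),
                 args = args,
                 package = "pathflowsim",
                 version = as.character(utils::packageVersion("pathflowsim")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' Write a tabular report as CSV and JSON with its manifest
#'
#' Machine consumption reads the JSON; the CSV mirrors the tabular
#' layout for human comparison. The manifest is written alongside as
#' `<name>_manifest.json`.
#'
#' @param tab Data frame to write.
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the three files.
#' @param manifest A [run_manifest()].
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(tab, out_dir, name, manifest) {
  stopifnot(is.data.frame(tab), inherits(manifest, "run_manifest"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, paste0(name, ".csv"))
  js <- file.path(out_dir, paste0(name, ".json"))
  mf <- file.path(out_dir, paste0(name, "_manifest.json"))
  utils::write.csv(tab, csv, row.names = FALSE)
  jsonlite::write_json(tab, js, dataframe = "rows", digits = NA,
                       na = "null")
  jsonlite::write_json(unclass(manifest), mf, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv, js, mf))
}

cli_usage <- function() {
  paste(
    "usage: pathflowsim <command> [options]",
    "",
    "commands:",
    "  simulate   run the workflow simulation on the reference process",
    "  capacity   installed-productive-capacity and staffing report",
    "  scenarios  cost-benefit comparison of the output plans",
    "  validate   paired model-validation interval from a 2-column CSV",
    "  synth      generate a synthetic biopsy log",
    "  recover    generator/estimator recovery report",
    "",
    "options:",
    "  --seed N          random seed (default 1)",
    "  --replicates N    replicate count (command-specific default)",
    "  --out-dir DIR     output directory (default '.')",
    "  --config PATH     input file (validate: CSV with columns X,Y)",
    "  --counts A,B,C,D  combination counts for `capacity`",
    "  --weeks N         weeks for `synth`/`recover` (default 52)",
    "  --horizon N       simulation horizon hours (default 40)",
    "  --help            show this message",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  out <- list(seed = 1L, replicates = NA_integer_, out_dir = ".",
              config = NULL, counts = NULL, weeks = 52L, horizon = 40)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    grab <- function() {
      if (i + 1L > length(argv)) stop("missing value for ", a, call. = FALSE)
      argv[i + 1L]
    }
    switch(a,
           "--seed" = { out$seed <- as.integer(grab()); i <- i + 2L },
           "--replicates" = { out$replicates <- as.integer(grab()); i <- i + 2L },
           "--out-dir" = { out$out_dir <- grab(); i <- i + 2L },
           "--config" = { out$config <- grab(); i <- i + 2L },
           "--counts" = {
             out$counts <- as.numeric(strsplit(grab(), ",")[[1]])
             i <- i + 2L
           },
           "--weeks" = { out$weeks <- as.integer(grab()); i <- i + 2L },
           "--horizon" = { out$horizon <- as.numeric(grab()); i <- i + 2L },
           stop("unknown flag: ", a, call. = FALSE))
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `capacity`, `scenarios`,
#' `validate`, `synth`, and `recover`, writing CSV + JSON reports and a
#' run manifest into `--out-dir`. A thin Rscript wrapper is installed
#' under `inst/scripts/pathflowsim`.
#'
#' @param argv Character vector of command-line arguments (subcommand
#'   first), e.g. `c("capacity", "--seed", "7")`.
#' @return Integer exit code, invisibly: 0 on success, 2 on usage or
#'   validation errors.
#' @examples
#' out <- tempfile()
#' pathflowsim_main(c("scenarios", "--out-dir", out))
#' @export
pathflowsim_main <- function(argv = character()) {
  if (length(argv) == 0L || argv[1] %in% c("--help", "-h", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  cmd <- argv[1]
  known <- c("simulate", "capacity", "scenarios", "validate", "synth",
             "recover")
  res <- tryCatch({
    if (!cmd %in% known) stop("unknown command: ", cmd, call. = FALSE)
    opt <- parse_cli_args(argv[-1L])
    mf <- run_manifest(cmd, opt$seed,
                       opt[c("replicates", "weeks", "horizon", "counts")])
    switch(cmd,
      simulate = {
        reps <- if (is.na(opt$replicates)) 5L else opt$replicates
        proc <- remove_activities(fixture_pathology_process(stochastic = TRUE),
                                  c(6L, 32L))
        dem <- demand_spec(weekly_capacity(proc), 0)
        sim <- run_simulation(proc, dem, opt$horizon, reps, opt$seed)
        agg <- stats::aggregate(
          cbind(busy_hours, queue_hours, units_out, utilization) ~ id + category,
          data = sim$activity, FUN = mean)
        agg <- agg[order(agg$id), ]
        write_report(agg, opt$out_dir, "simulation", mf)
        message(sprintf("simulate: mean weekly completions %.1f",
                        mean(sim$summary$completions)))
      },
      capacity = {
        reps <- if (is.na(opt$replicates)) 10L else opt$replicates
        counts <- if (is.null(opt$counts)) pathology_combination_counts()
                  else opt$counts
        rep_c <- capacity_report(counts, replicates = reps, seed = opt$seed)
        tab <- rep_c$table
        tab$required_fte <- required_fte(tab$total_hours)
        write_report(tab, opt$out_dir, "capacity", mf)
        staff <- staffing_report(rep_c$grand_total_hours)
        write_report(staff, opt$out_dir, "staffing", mf)
        message(sprintf("capacity: grand total %.2f h (%.2f FTE)",
                        rep_c$grand_total_hours,
                        required_fte(rep_c$grand_total_hours)))
      },
      scenarios = {
        tab <- compare_scenarios(default_scenarios())
        write_report(tab, opt$out_dir, "scenarios", mf)
        message(sprintf("scenarios: best plan '%s' at %.2f US$/biopsy",
                        tab$name[1], tab$cost_per_biopsy[1]))
      },
      validate = {
        if (is.null(opt$config) || !file.exists(opt$config)) {
          stop("validate needs --config pointing to a CSV with columns X,Y",
               call. = FALSE)
        }
        d <- utils::read.csv(opt$config)
        v <- validation_interval(d$X, d$Y)
        tab <- data.frame(lo = v$interval["lo"], hi = v$interval["hi"],
                          contains_zero = v$contains_zero, valid = v$valid)
        write_report(tab, opt$out_dir, "validation", mf)
        message(sprintf("validate: interval (%.3f, %.3f), model %s",
                        v$interval["lo"], v$interval["hi"],
                        if (v$valid) "valid" else "rejected"))
      },
      synth = {
        cfg <- synthetic_config(weeks = opt$weeks, seed = opt$seed)
        log <- generate_biopsy_log(cfg)
        write_report(as.data.frame(log), opt$out_dir, "biopsy_log", mf)
        write_report(gap_series(log), opt$out_dir, "gap_series", mf)
        message(sprintf("synth: %d biopsies over %d weeks", nrow(log),
                        opt$weeks))
      },
      recover = {
        cfg <- synthetic_config(weeks = opt$weeks, seed = opt$seed)
        rec <- recovery_suite(cfg)
        tab <- data.frame(
          quantity = c("demand_mean", "demand_sd",
                       "cutting_p1", "analysis_p1",
                       "cutting_mu1", "cutting_mu2",
                       "analysis_mu1", "analysis_mu2"),
          truth = c(rec$demand$true_mean, rec$demand$true_sd,
                    rec$cutting$true_weights[1], rec$analysis$true_weights[1],
                    rec$cutting$true_means, rec$analysis$true_means),
          estimate = c(rec$demand$est_mean, rec$demand$est_sd,
                       rec$cutting$est_proportions[1],
                       rec$analysis$est_proportions[1],
                       rec$cutting$est_means, rec$analysis$est_means))
        write_report(tab, opt$out_dir, "recovery", mf)
        message(sprintf("recover: demand mean estimated %.2f (true %.2f)",
                        rec$demand$est_mean, rec$demand$true_mean))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(res)
}
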