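# Configuration files, deterministic output writing and the command-line
# surface. The CLI itself is a thin Rscript (inst/cli/uorfsim.R) over
# run_cli().

experiment_kinds <- c("run", "sweep", "grid", "thresholds", "oracle-check",
                      "profiling", "fixtures")

#' Parse an experiment configuration file
#'
#' YAML with top-level keys `experiment` (one of `run`, `sweep`, `grid`,
#' `thresholds`, `oracle-check`, `profiling`, `fixtures`), `params`
#' (overrides of [sim_params()] fields), and, where relevant, `varying`,
#' `values`, `criterion` (`nonmonotonic`, `no_resistance`,
#' `max_relative_below`), `cutoff`, `grid_points`, `out_dir`, `seed`,
#' plus `n`, `effect_size`, `noise` for profiling fixtures. Unknown keys
#' and out-of-range values are rejected with the offending name.
#'
#' @param path Configuration file path.
#' @return An `experiment_config`: validated list with all defaults
#'   resolved.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("experiment", "params", "varying", "values", "criterion",
             "cutoff", "grid_points", "out_dir", "seed", "n",
             "effect_size", "noise")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$experiment) || !raw$experiment %in% experiment_kinds)
    stop("experiment must be one of: ", paste(experiment_kinds,
                                              collapse = ", "))

  par_over <- raw$params
  if (!is.null(par_over)) {
    bad <- setdiff(names(par_over), names(formals(sim_params)))
    if (length(bad))
      stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$seed)) par_over$seed <- raw$seed
  params <- do.call(sim_params, as.list(par_over))  # validates ranges

  cfg <- list(
    experiment = raw$experiment,
    params = params,
    varying = raw$varying,
    values = raw$values,
    criterion = if (is.null(raw$criterion)) "nonmonotonic" else raw$criterion,
    cutoff = if (is.null(raw$cutoff)) 1.05 else raw$cutoff,
    grid_points = if (is.null(raw$grid_points)) 20L else
      as.integer(raw$grid_points),
    out_dir = if (is.null(raw$out_dir)) "." else raw$out_dir,
    n = if (is.null(raw$n)) 325L else as.integer(raw$n),
    effect_size = if (is.null(raw$effect_size)) 0.5 else raw$effect_size,
    noise = if (is.null(raw$noise)) 1 else raw$noise
  )
  if (cfg$grid_points < 2)
    stop("grid_points must be at least 2 (the grid must contain 0.1 and 0)")
  if (!cfg$criterion %in% c("nonmonotonic", "no_resistance",
                            "max_relative_below"))
    stop("unknown criterion: ", cfg$criterion)
  if (cfg$experiment %in% c("grid", "thresholds")) {
    if (is.null(cfg$varying) || is.null(cfg$values))
      stop("experiment '", cfg$experiment,
           "' requires 'varying' and 'values'")
    if (!cfg$varying %in% names(formals(sim_params)))
      stop("unknown parameter name in 'varying': ", cfg$varying)
  }
  structure(cfg, class = "experiment_config")
}

#' Write an experiment configuration file
#'
#' Inverse of [parse_config()]: the written file parses back to an
#' identical configuration.
#'
#' @param cfg An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  par <- unclass(cfg$params)
  par <- par[setdiff(names(par), c("start_site", "stop_site", "exit_site"))]
  out <- list(experiment = cfg$experiment, params = par,
              varying = cfg$varying, values = cfg$values,
              criterion = cfg$criterion, cutoff = cfg$cutoff,
              grid_points = cfg$grid_points, out_dir = cfg$out_dir,
              n = cfg$n, effect_size = cfg$effect_size, noise = cfg$noise)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

config_criterion <- function(cfg) {
  switch(cfg$criterion,
         nonmonotonic = criterion_nonmonotonic(),
         no_resistance = criterion_no_resistance(),
         max_relative_below = criterion_max_relative_below(cfg$cutoff))
}

fmt10 <- function(x) {
  if (is.numeric(x)) signif(x, 10) else x
}

#' Write a response curve as CSV
#'
#' Columns `r_in`, `r_out`, `r_out_se`, `relative`, `relative_se`,
#' `realized_load_rate`, numerics at 10 significant digits; when the
#' curve came from a [grid_experiment()] a leading `value` column carries
#' the varied parameter.
#'
#' @param curve A `response_curve`, or a `grid_experiment` whose curves
#'   are stacked.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  if (inherits(curve, "grid_experiment")) {
    tab <- do.call(rbind, lapply(names(curve$curves), function(v) {
      cbind(value = v, as.data.frame(curve$curves[[v]]))
    }))
  } else {
    stopifnot(inherits(curve, "response_curve"))
    tab <- as.data.frame(curve)
  }
  tab[] <- lapply(tab, fmt10)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

write_json_sorted <- function(x, path) {
  x <- x[order(names(x))]
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

provenance_sidecar <- function(cfg, path) {
  par <- unclass(cfg$params)
  par <- par[setdiff(names(par), c("start_site", "stop_site", "exit_site"))]
  write_json_sorted(list(
    experiment = cfg$experiment,
    params = par,
    seed = cfg$params$seed,
    package_version = as.character(utils::packageVersion("uorfsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), path)
}

cli_log <- function(...) message("[uorfsim] ", sprintf(...))

#' Command-line entry point
#'
#' `run_cli(c("<subcommand>", "--config", "cfg.yaml"))` executes one
#' experiment described by a configuration file and writes CSV/JSON
#' outputs plus a provenance sidecar into the configured output
#' directory. Subcommands: `run`, `sweep`, `grid`, `thresholds`,
#' `oracle-check`, `profiling`, `fixtures`. An `--out-dir` option
#' overrides the configured directory. The installed script
#' `system.file("cli", "uorfsim.R", package = "uorfsim")` wraps this
#' function for shell use.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code (0 on success), invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: uorfsim <", paste(experiment_kinds, collapse = "|"),
    "> --config FILE [--out-dir DIR]")
  fail <- function(...) {
    message(...)
    message(usage)
    return(invisible(1L))
  }
  if (!length(argv)) return(fail("no subcommand given"))
  sub <- argv[1]
  if (!sub %in% experiment_kinds)
    return(fail("unknown subcommand: ", sub))
  opts <- argv[-1]
  getopt <- function(flag) {
    i <- which(opts == flag)
    if (length(i) && i[1] < length(opts)) opts[i[1] + 1] else NULL
  }
  cfg_path <- getopt("--config")
  if (is.null(cfg_path)) return(fail("--config FILE is required"))

  code <- tryCatch({
    cfg <- parse_config(cfg_path)
    cfg$experiment <- sub
    out_dir <- getopt("--out-dir")
    if (!is.null(out_dir)) cfg$out_dir <- out_dir
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    run_experiment(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

#' Execute one configured experiment
#'
#' The programmatic core of [run_cli()]: dispatches on
#' `cfg$experiment` and writes the outputs into `cfg$out_dir`.
#'
#' @param cfg An `experiment_config` from [parse_config()].
#' @return Paths of the written files, invisibly.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  od <- cfg$out_dir
  grid <- default_rin_grid(cfg$grid_points)
  out <- character()
  w <- function(p) { out <<- c(out, p); p }

  if (cfg$experiment == "run") {
    cli_log("single run: %g tacts", cfg$params$n_tacts)
    res <- run_simulation(cfg$params, occupancy = TRUE)
    result_to_json(res, w(file.path(od, "run.json")))
    utils::write.csv(occupancy_profile(res),
                     w(file.path(od, "occupancy.csv")), row.names = FALSE)
  } else if (cfg$experiment == "sweep") {
    cli_log("r_in sweep: %d points", length(grid))
    cv <- sweep_rin(cfg$params, r_in = grid)
    write_curve_csv(cv, w(file.path(od, "sweep.csv")))
    write_json_sorted(c(find_max(cv),
                        list(nonmonotonic = detect_nonmonotonic(cv))),
                      w(file.path(od, "sweep_summary.json")))
  } else if (cfg$experiment %in% c("grid", "thresholds")) {
    cli_log("%s over '%s' (%d values)", cfg$experiment, cfg$varying,
            length(cfg$values))
    if (cfg$experiment == "grid") {
      ex <- grid_experiment(cfg$varying, cfg$values, cfg$params, r_in = grid)
      write_curve_csv(ex, w(file.path(od, "grid.csv")))
      tab <- ex$summary
      tab[] <- lapply(tab, fmt10)
      utils::write.csv(tab, w(file.path(od, "grid_summary.csv")),
                       row.names = FALSE)
    } else {
      ts <- threshold_scan(cfg$varying, cfg$values, config_criterion(cfg),
                           cfg$params, r_in = grid)
      write_json_sorted(list(varying = ts$varying, values = ts$values,
                             flags = ts$flags, threshold = ts$threshold,
                             last_before = ts$last_before,
                             criterion = cfg$criterion),
                        w(file.path(od, "thresholds.json")))
    }
  } else if (cfg$experiment == "oracle-check") {
    cli_log("oracle check on %d small instances", 5L)
    rep <- oracle_check()
    tab <- rep
    tab[] <- lapply(tab, fmt10)
    utils::write.csv(tab, w(file.path(od, "oracle_check.csv")),
                     row.names = FALSE)
  } else if (cfg$experiment == "fixtures") {
    cli_log("synthetic profiling cohort: n=%d", cfg$n)
    cohort <- generate_synthetic_profiles(cfg$n, cfg$effect_size, cfg$noise,
                                          seed = cfg$params$seed)
    utils::write.table(cohort$records,
                       w(file.path(od, "synthetic_records.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (cfg$experiment == "profiling") {
    cli_log("profiling metrics: n=%d", cfg$n)
    cohort <- generate_synthetic_profiles(cfg$n, cfg$effect_size, cfg$noise,
                                          seed = cfg$params$seed)
    rec <- binned_zscores(cohort$records)
    rep <- correlate_features(rec$uorf_length, rec$zscore)
    utils::write.table(rec, w(file.path(od, "profiling_records.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_json_sorted(rep, w(file.path(od, "profiling_correlations.json")))
  }
  provenance_sidecar(cfg, w(file.path(od, "provenance.json")))
  invisible(out)
}
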