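#' Read and validate a pipeline configuration file
#'
#' One YAML (or JSON) file governs all stages. Recognized top-level
#' sections: `simulate` (fields of [sim_config()] except `components` /
#' `gender_effects`, which keep their defaults), `preprocess` (fields of
#' [preprocess_config()]), `evaluate` (scalar fields of
#' [evaluation_config()]), and `seed`. Missing sections fall back to
#' defaults. Validation errors name the offending field; in particular a
#' band edge at or above half the sampling rate is rejected by name
#' (Nyquist).
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` configuration file.
#' @return List with elements `simulate`, `preprocess`, `evaluate`,
#'   `seed`.
#' @export
read_pipeline_config <- function(path) {
  raw <- switch(tolower(tools::file_ext(path)),
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be .yaml, .yml or .json", call. = FALSE))
  raw <- raw %||% list()
  build <- function(fun, args, section) {
    args <- args %||% list()
    bad <- setdiff(names(args), names(formals(fun)))
    if (length(bad)) {
      stop("unknown field(s) in config section '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(fun, args)
  }
  sim <- build(sim_config, raw$simulate, "simulate")
  pre <- build(preprocess_config, raw$preprocess, "preprocess")
  if (pre$high_hz >= sim$fs / 2) {
    stop("preprocess.high_hz (", pre$high_hz,
         " Hz) is at or above the Nyquist frequency (", sim$fs / 2, " Hz)",
         call. = FALSE)
  }
  ev_args <- raw$evaluate %||% list()
  if (!is.null(ev_args$classifiers)) {
    ev_args$classifiers <- lapply(ev_args$classifiers, function(kind) {
      classifier_spec(kind)
    })
  }
  ev <- build(evaluation_config, ev_args, "evaluate")
  list(simulate = sim, preprocess = pre, evaluate = ev,
       seed = as.integer(raw$seed %||% 1L))
}

#' Run the simulate-preprocess-evaluate pipeline end to end
#'
#' Simulates a cohort (or loads one from `cohort_dir`), preprocesses it
#' into difference waveforms, runs the leave-one-out decoding experiment,
#' writes the report tables plus a run manifest, and returns the report.
#' The manifest records the configuration hash, the seed, and every file
#' written, so a run can be reproduced exactly.
#'
#' @param config Either a path to a config file (see
#'   [read_pipeline_config()]) or a list as returned by it.
#' @param out_dir Output directory.
#' @param cohort_dir Optional directory of preprocessed difference
#'   waveforms ([write_cohort()] layout) to evaluate instead of
#'   simulating.
#' @param verbose Log stage progress to stderr.
#' @return A [run_experiment()] report, invisibly; side effect: files
#'   under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, cohort_dir = NULL, verbose = TRUE) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(cohort_dir)) {
    say("simulate: %d persons, seed %d", cfg$simulate$n_persons, cfg$seed)
    raw <- simulate_cohort(cfg$simulate, seed = cfg$seed)
    say("preprocess: filtering, blink correction, epoching, rejection")
    cohort <- preprocess_cohort(raw, cfg$preprocess, verbose = verbose)
  } else {
    say("loading cohort from %s", cohort_dir)
    cohort <- read_cohort(cohort_dir)
  }
  cohort_files <- write_cohort(cohort, file.path(out_dir, "cohort"))
  say("evaluate: %d classifiers x leave-one-out", length(cfg$evaluate$classifiers))
  report <- run_experiment(cohort, cfg$evaluate)
  report_files <- write_report(report, out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("erpdecode")),
    seed = cfg$seed,
    config_hash = .config_hash(cfg),
    stages = if (is.null(cohort_dir)) c("simulate", "preprocess", "evaluate")
             else c("load", "evaluate"),
    inputs = cohort_dir %||% character(0),
    outputs = c(cohort_files, report_files),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

# stable hash of the resolved configuration (serialization md5)
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
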