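# Recognised run-configuration schema: names and sub-names.
run_schema <- function() {
  list(
    seed = NULL, outdir = NULL, stages = NULL,
    simulate = c("n_per_cohort", "cohorts", "frame_rate", "duration",
                 "sigma0", "sigma0_sd", "c_nm_bp", "tau", "unwindable_bp",
                 "dead_time", "t_bind_range", "drift_nm_s", "p_pause",
                 "pause_dur", "asym_frac"),
    process = c("window_frames", "stride", "drift_window_s", "qc_frames"),
    detect = c("c_nm_bp", "smooth", "gap", "persistence", "plateau_min_s",
               "qualify_span_s", "qualify_level"),
    kinetics = c("resamples")
  )
}

validate_run_config <- function(config) {
  schema <- run_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sect in c("simulate", "process", "detect", "kinetics")) {
    if (is.null(config[[sect]])) next
    bad <- setdiff(names(config[[sect]]), schema[[sect]])
    if (length(bad))
      stop("unknown key(s) in '", sect, "': ", paste(bad, collapse = ", "))
  }
  if (is.null(config$outdir)) stop("configuration must set 'outdir'")
  config
}

#' Read a pipeline run configuration
#'
#' YAML (or JSON) file with top-level keys `seed`, `outdir`, `stages`
#' (subset of `simulate`, `process`, `detect`, `kinetics`) and per-stage
#' parameter blocks. Unknown keys are rejected by name.
#'
#' @param path Configuration file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_run_config(cfg)
}

# Per-stage substreams derived from one global seed, so stages can be re-run
# independently yet reproducibly.
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, process = 211L, detect = 307L, kinetics = 401L)
  (as.integer(seed) + offs[[stage]] * 10007L) %% .Machine$integer.max
}

#' Run the smTPM analysis pipeline
#'
#' Executes the configured stages in order — `simulate` (synthetic cohorts),
#' `process` (drift correction, symmetry QC, BM series, calibration cohorts),
#' `detect` (per-molecule unwinding events) and `kinetics` (cohort
#' velocities, bootstrap, fold changes) — writing per-stage outputs and a
#' run manifest into `outdir`. Rerunning with the same configuration and
#' seed reproduces all stochastic outputs exactly.
#'
#' @param config Configuration list (see [read_run_config()]) or a path to a
#'   YAML/JSON configuration file.
#' @return The run manifest (also written to `outdir/manifest.json`),
#'   invisibly. Its `results` entry holds the kinetics report as a data
#'   frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "process", "detect", "kinetics")
  seed <- config$seed %||% 1L
  files <- character(0)
  results <- list()

  sim <- config$simulate %||% list()
  cohorts <- sim$cohorts %||% list(list(label = "wt", v_bp_s = 3.58,
                                        p_unwind = 1))
  n_per <- sim$n_per_cohort %||% 15L
  base_args <- sim[setdiff(names(sim), c("cohorts", "n_per_cohort"))]

  trajs_by_cohort <- list()
  if ("simulate" %in% stages) {
    for (i in seq_along(cohorts)) {
      co <- cohorts[[i]]
      label <- co$label %||% paste0("cohort", i)
      args <- modifyList(base_args,
                         co[setdiff(names(co), "label")])
      args$seed <- stage_seed(seed, "simulate") + i
      cfg <- do.call(tpm_config, args)
      trajs <- simulate_cohort(cfg, n_per, label = label)
      f <- file.path(outdir, paste0("trajectories-", label, ".csv"))
      write_trajectories(trajs, f)
      files <- c(files, f)
      trajs_by_cohort[[label]] <- trajs
    }
  }

  proc <- config$process %||% list()
  series_by_cohort <- list()
  if ("process" %in% stages && length(trajs_by_cohort)) {
    for (label in names(trajs_by_cohort)) {
      trajs <- lapply(trajs_by_cohort[[label]], correct_drift,
                      drift_window_s = proc$drift_window_s %||% 10)
      sl <- lapply(trajs, function(tr) {
        try(bm_series(tr, window_frames = proc$window_frames %||% 20,
                      stride = proc$stride %||% 20), silent = TRUE)
      })
      sl <- sl[!vapply(sl, inherits, logical(1), "try-error")]
      f <- file.path(outdir, paste0("bm-", label, ".csv"))
      write_bm_series(sl, f)
      files <- c(files, f)
      series_by_cohort[[label]] <- sl
    }
  }

  det <- config$detect %||% list()
  events_by_cohort <- list()
  if ("detect" %in% stages && length(trajs_by_cohort)) {
    for (label in names(trajs_by_cohort)) {
      ev <- unwind_events(
        trajs_by_cohort[[label]],
        c_nm_bp = det$c_nm_bp %||% 0.0718,
        window_frames = proc$window_frames %||% 20,
        stride = proc$stride %||% 20,
        drift_window_s = proc$drift_window_s %||% 10,
        smooth = det$smooth %||% 15, gap = det$gap %||% 8,
        persistence = det$persistence %||% 15,
        plateau_min_s = det$plateau_min_s %||% 15,
        qualify_span_s = det$qualify_span_s %||% 30,
        qualify_level = det$qualify_level %||% 0.05)
      f <- file.path(outdir, paste0("events-", label, ".tsv"))
      write_events(ev, f)
      files <- c(files, f)
      events_by_cohort[[label]] <- ev
    }
  }

  if ("kinetics" %in% stages && length(events_by_cohort)) {
    kin <- config$kinetics %||% list()
    rows <- list()
    ref_mean <- NULL
    for (label in names(events_by_cohort)) {
      v <- cohort_velocities(events_by_cohort[[label]])
      if (length(v) >= 2) {
        bs <- bootstrap_mean(v, resamples = kin$resamples %||% 100,
                             seed = stage_seed(seed, "kinetics"))
        if (is.null(ref_mean)) ref_mean <- mean(v)
        rows[[label]] <- data.frame(
          condition = label, n = length(v), v_mean = mean(v), v_sd = sd(v),
          boot_mean = bs$mean, boot_sd = bs$sd,
          fold = mean(v) / ref_mean)
      }
    }
    if (length(rows)) {
      report <- do.call(rbind, rows)
      f <- file.path(outdir, "kinetics-report.tsv")
      write.table(report, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
      results$report <- report
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("smtpm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, stages = stages,
    config = config[setdiff(names(config), "outdir")],
    files = lapply(setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))),
    results = results)
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "results")],
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
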