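# End-to-end orchestration: simulate (or read) cohorts, derive the healthy
# threshold, stratify the patient cohort, run the cross-correlation screen,
# run the EAE timing analysis, and emit stage outputs plus one
# machine-readable JSON report. All warnings surfaced by the stages are
# embedded in the report so downstream checks can assert on them.

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `input` (a long-format cohort CSV) or `simulation` (a list
#' with optional `healthy`, `ms`, `eae` generator configurations) must be
#' given. With `simulation`, generator seeds are derived from `seed` so one
#' integer reproduces the whole run.
#'
#' @param input Path to a cohort CSV written by [write_cohort_csv()], or
#'   `NULL`.
#' @param simulation List with entries `healthy` (arguments for
#'   [generate_healthy_cohort()]), `ms` (an [ms_cohort_config()]), `eae` (an
#'   [eae_cohort_config()]); any subset may be omitted. `NULL` when reading
#'   from `input`.
#' @param x_variable Driving series for the screen.
#' @param y_variables Comparison variables (`NULL` = all others).
#' @param max_lag Lag window half-width.
#' @param alpha Significance / FDR level in (0, 1).
#' @param threshold `"estimate"` to derive the healthy-variation threshold
#'   from the healthy cohort, or a fixed positive percent value.
#' @param min_duration Sustained-contraction window, intervals.
#' @param fdr_pool `"all"` or `"nominal"`.
#' @param seed Master integer seed.
#' @param output_dir Directory for stage outputs; created if needed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            x_variable = "ventricle_volume",
                            y_variables = NULL, max_lag = 2L, alpha = 0.05,
                            threshold = 6, min_duration = 2L,
                            fdr_pool = "all", seed = 1L,
                            output_dir = tempfile("vvdyn_run")) {
  if (is.null(input) == is.null(simulation)) {
    stop("exactly one of 'input' and 'simulation' must be given")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!identical(threshold, "estimate") &&
      (!is.numeric(threshold) || threshold <= 0)) {
    stop("threshold must be a positive percent value or \"estimate\"")
  }
  structure(list(input = input, simulation = simulation,
                 x_variable = x_variable, y_variables = y_variables,
                 max_lag = as.integer(max_lag), alpha = alpha,
                 threshold = threshold, min_duration = as.integer(min_duration),
                 fdr_pool = fdr_pool, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File whose extension selects the parser (`.yml`/`.yaml` or
#'   `.json`). Fields mirror the arguments of [pipeline_config()];
#'   `simulation$ms` and `simulation$eae` entries are passed to the
#'   respective config constructors.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim <- raw$simulation
  if (!is.null(sim)) {
    if (!is.null(sim$ms)) sim$ms <- do.call(ms_cohort_config, sim$ms)
    if (!is.null(sim$eae)) sim$eae <- do.call(eae_cohort_config, sim$eae)
    raw$simulation <- sim
  }
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

# collect warnings raised by an expression, returning value + messages
with_collected_warnings <- function(expr) {
  msgs <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = msgs)
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> threshold -> stratify -> cross-correlation screen ->
#' EAE timing, writing every stage output under `config$output_dir` and a
#' single JSON report (`report.json`) whose numbers are all recomputable
#' from the stage files. Deterministic given `config$seed`; the report's
#' only run-specific field is its `timestamp`.
#'
#' @param config A [pipeline_config()] (or path to a YAML/JSON file).
#' @return Invisibly, a list of class `vvdyn_report` with the report and the
#'   paths of the files written.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  files <- character(0)
  warnings <- character(0)

  healthy <- ms <- eae <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    if (!is.null(sim$healthy)) {
      args <- sim$healthy
      args$seed <- substream_seed(config$seed, 101L)
      healthy <- do.call(generate_healthy_cohort, args)
    }
    if (!is.null(sim$ms)) {
      cfg <- sim$ms
      cfg$seed <- substream_seed(config$seed, 202L)
      ms <- generate_ms_cohort(cfg)
    }
    if (!is.null(sim$eae)) {
      cfg <- sim$eae
      cfg$seed <- substream_seed(config$seed, 303L)
      eae <- generate_eae_cohort(cfg)
    }
  } else {
    full <- read_cohort_csv(config$input)
    grp <- vapply(full, `[[`, "", "group")
    if (any(grp == "healthy")) healthy <- full[grp == "healthy"]
    if (any(grp == "ms")) ms <- full[grp == "ms"]
    if (any(grp == "eae")) eae <- full[grp == "eae"]
  }
  if (is.null(ms) && is.null(eae)) {
    stop("empty cohort: nothing to analyse")
  }
  for (nm in c("healthy", "ms", "eae")) {
    co <- get(nm)
    if (!is.null(co)) {
      write_cohort_csv(co, out(paste0(nm, "_cohort.csv")))
      files <- c(files, out(paste0(nm, "_cohort.csv")))
    }
  }

  if (identical(config$threshold, "estimate")) {
    if (is.null(healthy)) stop("threshold = \"estimate\" needs a healthy cohort")
    thr <- estimate_normal_variation_threshold(healthy)
  } else {
    thr <- structure(list(value = config$threshold, source = "fixed",
                          per_subject_maxima = numeric(0)),
                     class = "threshold_estimate")
  }

  strat <- screen <- NULL
  if (!is.null(ms)) {
    sr <- with_collected_warnings(
      stratify_cohort(ms, thr, min_duration = config$min_duration))
    strat <- sr$value
    warnings <- c(warnings, sr$warnings)
    utils::write.csv(strat$table, out("vv_events.csv"), row.names = FALSE)
    utils::write.csv(strat$lollipop, out("vv_lollipop.csv"), row.names = FALSE)
    files <- c(files, out("vv_events.csv"), out("vv_lollipop.csv"))

    sc <- with_collected_warnings(
      run_ccf_screen(ms, x_variable = config$x_variable,
                     y_variables = config$y_variables,
                     max_lag = config$max_lag, alpha = config$alpha,
                     fdr_pool = config$fdr_pool))
    screen <- sc$value
    warnings <- c(warnings, sc$warnings)
    utils::write.csv(screen$records, out("ccf_records.csv"), row.names = FALSE)
    files <- c(files, out("ccf_records.csv"))
  }

  timing <- NULL
  if (!is.null(eae)) {
    tr <- with_collected_warnings(
      eae_timing_analysis(eae, vv_threshold = thr$value))
    timing <- tr$value
    warnings <- c(warnings, tr$warnings)
    utils::write.csv(timing$events, out("eae_events.csv"), row.names = FALSE)
    surv_tab <- do.call(rbind, lapply(names(timing$km), function(nm) {
      cbind(event = nm, timing$km[[nm]])
    }))
    utils::write.csv(surv_tab, out("eae_survival.csv"), row.names = FALSE)
    files <- c(files, out("eae_events.csv"), out("eae_survival.csv"))
  }

  report <- list(
    versions = list(
      package = as.character(utils::packageVersion("vvdyn")),
      r = paste(R.version$major, R.version$minor, sep = ".")),
    config = list(
      x_variable = config$x_variable, max_lag = config$max_lag,
      alpha = config$alpha, fdr_pool = config$fdr_pool,
      threshold = thr$value, threshold_source = thr$source,
      min_duration = config$min_duration, seed = config$seed),
    cohort_counts = list(
      healthy = if (is.null(healthy)) 0L else length(healthy),
      ms = if (is.null(ms)) 0L else length(ms),
      eae = if (is.null(eae)) 0L else length(eae)),
    stratification = if (is.null(strat)) NULL else list(
      contracting = unname(strat$group_sizes[["contracting"]]),
      noncontracting = unname(strat$group_sizes[["noncontracting"]]),
      expansion_only = strat$n_expansion_only,
      prop_any_monthly_change = strat$prop_any_monthly_change,
      excluded = strat$n_excluded),
    screen = if (is.null(screen)) NULL else list(
      total_coefficients = screen$summary$total_coefficients,
      n_undefined = screen$summary$n_undefined,
      n_nominal = screen$summary$n_nominal,
      n_fdr_retained = screen$summary$n_fdr_retained,
      n_adf_failures = screen$summary$n_adf_failures,
      n_periodicity_flags = screen$summary$n_periodicity_flags,
      n_skipped = screen$summary$n_skipped),
    eae_timing = if (is.null(timing)) NULL else list(
      median_vv_onset = stats::median(timing$events$t_vv_onset),
      median_dt1_max = stats::median(timing$events$t_dt1_max),
      median_clinical_onset = stats::median(timing$events$t_clinical_onset),
      median_weight_nadir = stats::median(timing$events$t_weight_nadir),
      logrank = timing$logrank),
    warnings = warnings,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files <- c(files, out("report.json"))
  invisible(structure(list(report = report, files = files,
                           stratification = strat, screen = screen,
                           timing = timing),
                      class = "vvdyn_report"))
}

#' @export
print.vvdyn_report <- function(x, ...) {
  r <- x$report
  cat("<vvdyn_report> cohorts: healthy ", r$cohort_counts$healthy,
      ", ms ", r$cohort_counts$ms, ", eae ", r$cohort_counts$eae, "\n",
      sep = "")
  if (!is.null(r$stratification)) {
    cat(sprintf("  stratification: %d contracting / %d noncontracting (threshold %.3g%%)\n",
                r$stratification$contracting, r$stratification$noncontracting,
                r$config$threshold))
  }
  if (!is.null(r$screen)) {
    cat(sprintf("  screen: %d coefficients, %d nominal, %d FDR-retained\n",
                r$screen$total_coefficients, r$screen$n_nominal,
                r$screen$n_fdr_retained))
  }
  if (!is.null(r$eae_timing)) {
    cat(sprintf("  EAE medians (d): VV onset %g, dT1 max %g, clinical onset %g\n",
                r$eae_timing$median_vv_onset, r$eae_timing$median_dt1_max,
                r$eae_timing$median_clinical_onset))
  }
  if (length(r$warnings)) cat("  warnings:", length(r$warnings), "\n")
  cat("  outputs:", length(x$files), "files\n")
  invisible(x)
}
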