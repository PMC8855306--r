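#' Run the full profiling pipeline and write its artifacts
#'
#' Orchestrates simulate (optional) -> QC -> ensemble profiles -> cohort
#' summary, writing every artifact plus a machine-readable run manifest to
#' `out_dir`:
#' \itemize{
#'   \item `cohort/` -- the input cohort in interchange format (when
#'     simulated here);
#'   \item `filter_report.json` -- the inclusion-filter report;
#'   \item `profile_hr.csv`, `profile_anxiety.csv` -- ensemble profiles
#'     (`t_seconds,mean,n`);
#'   \item `summary.json` -- the cohort summary statistics;
#'   \item `manifest.json` -- parameters, seed and package version, from
#'     which the whole run is reproducible.
#' }
#' If QC leaves no included recording, the filter report is still written
#' and an error is raised.
#'
#' @param cohort A `"pa_cohort"`, a directory containing one in
#'   interchange format, or `NULL` to simulate from `config`.
#' @param out_dir Output directory (created if needed).
#' @param config A [generator_config()] used when `cohort` is `NULL`.
#' @param min_hr_samples,prominence_bpm QC parameters.
#' @param window,dt,order,cutoff_hz Gridding and smoothing parameters.
#' @param recovery_threshold_bpm Recovery threshold for the summary.
#' @return The `"pa_cohort_summary"`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cohort = NULL, out_dir,
                         config = generator_config(),
                         min_hr_samples = 4, prominence_bpm = 5,
                         window = c(-15, 60), dt = 0.01,
                         order = 4, cutoff_hz = 0.1,
                         recovery_threshold_bpm = 85) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  simulated <- FALSE
  if (is.null(cohort)) {
    cohort <- generate_cohort(config)
    simulated <- TRUE
    write_cohort(cohort, file.path(out_dir, "cohort"))
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  qc <- qc_filter(cohort, min_hr_samples = min_hr_samples,
                  prominence_bpm = prominence_bpm)
  jsonlite::write_json(as.list(qc$report),
                       file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (qc$report$n_included == 0) {
    abort("No recording passed the inclusion filter; report written.")
  }
  for (ch in c("hr", "anxiety")) {
    prof <- tryCatch(
      profile_cohort(qc, channel = ch, window = window, dt = dt,
                     order = order, cutoff_hz = cutoff_hz),
      error = function(e) NULL
    )
    if (!is.null(prof)) {
      readr::write_csv(
        tibble::tibble(t_seconds = prof$t, mean = prof$mean, n = prof$n),
        file.path(out_dir, paste0("profile_", ch, ".csv"))
      )
    }
  }
  summ <- cohort_summary(cohort,
                         recovery_threshold_bpm = recovery_threshold_bpm,
                         min_hr_samples = min_hr_samples,
                         prominence_bpm = prominence_bpm)
  jsonlite::write_json(
    list(
      filter_report = as.list(summ$report),
      peak_hr = as.list(summ$peaks),
      duration = as.list(summ$durations),
      recovery_time_s = summ$recovery_time_s,
      ensemble_amplitude_bpm = summ$ensemble_amplitude_bpm,
      cycles_median = summ$cycles_median,
      anxiety_slope = if (is.null(summ$anxiety_slope)) NULL else
        summ$anxiety_slope[c("slope", "se", "p_value", "n_points")],
      lifestyle = summ$lifestyle,
      triggers = summ$triggers
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows"
  )
  manifest <- list(
    package = "panicprofiler",
    version = as.character(utils::packageVersion("panicprofiler")),
    simulated = simulated,
    config = if (simulated) unclass(config) else NULL,
    parameters = list(
      min_hr_samples = min_hr_samples, prominence_bpm = prominence_bpm,
      window = window, dt = dt, order = order, cutoff_hz = cutoff_hz,
      recovery_threshold_bpm = recovery_threshold_bpm
    ),
    n_included = summ$report$n_included
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(summ)
}
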