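#' Pooled anxiety recovery slope from peak HR onward
#'
#' Ordinary least squares of the raw anxiety ratings on time in minutes
#' since each recording's first HR peak, pooled over all recordings and
#' restricted to t >= 0 (peak HR to attack end). The regression is run on
#' the sparse raw ratings, not on interpolated grid values, so observations
#' are not pseudo-replicated.
#'
#' Because ratings within a recording share that recording's level, the
#' reported standard error is cluster-robust (sandwich estimator clustered
#' by recording); the model-based OLS standard error would understate the
#' uncertainty of the pooled slope.
#'
#' @param cohort A `"pa_cohort"` (normally the QC-included cohort).
#' @param peaks Per-recording peak locations, e.g. `qc_filter(...)$peaks`
#'   (columns `user_id`, `attack_index`, `t_seconds`).
#' @return A `"pa_slope_fit"` with fields `slope` (rating units / min),
#'   `se` (cluster-robust), `p_value` (t test on clusters - 1 df),
#'   `n_points`, `n_recordings`, and the underlying `lm` fit. Supports
#'   [tidy()] and [glance()].
#' @export
anxiety_slope <- function(cohort, peaks) {
  obs <- cohort$samples |>
    dplyr::filter(.data$channel == "anxiety") |>
    dplyr::inner_join(
      dplyr::select(peaks, "user_id", "attack_index", peak_t = "t_seconds"),
      by = c("user_id", "attack_index")
    ) |>
    dplyr::mutate(t_min = (.data$t_seconds - .data$peak_t) / 60) |>
    dplyr::filter(.data$t_min >= 0)
  if (nrow(obs) < 2 || length(unique(obs$t_min)) < 2) {
    abort("Anxiety slope needs >= 2 observations at distinct times after the peak.")
  }
  fit <- lm(value ~ t_min, data = obs)
  cl <- interaction(obs$user_id, obs$attack_index, drop = TRUE)
  g <- nlevels(cl)
  slope <- unname(coef(fit)["t_min"])
  se <- if (g > 1) {
    sqrt(sandwich::vcovCL(fit, cluster = cl)["t_min", "t_min"])
  } else {
    unname(summary(fit)$coefficients["t_min", "Std. Error"])
  }
  p <- if (se == 0) {
    if (slope == 0) 1 else 0
  } else {
    2 * stats::pt(-abs(slope / se), df = max(g - 1, 1))
  }
  structure(
    list(slope = slope, se = se, p_value = p,
         n_points = nrow(obs), n_recordings = g, model = fit),
    class = "pa_slope_fit"
  )
}

#' @export
print.pa_slope_fit <- function(x, ...) {
  cat(sprintf(
    "<pa_slope_fit> anxiety recovery slope %.3f rating/min (SE %.4f, p = %.3g, n = %d)\n",
    x$slope, x$se, x$p_value, x$n_points))
  invisible(x)
}

#' @rdname anxiety_slope
#' @param x A `"pa_slope_fit"`.
#' @param ... Unused.
#' @export
tidy.pa_slope_fit <- function(x, ...) {
  tibble::tibble(term = "t_min", estimate = x$slope, std.error = x$se,
                 p.value = x$p_value)
}

#' @rdname anxiety_slope
#' @export
glance.pa_slope_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 nobs = x$n_points)
}

#' Peak-HR summary over included recordings
#'
#' @param peaks Tibble of detected peaks with column `hr_at_peak`
#'   (e.g. `qc_filter(...)$peaks`).
#' @return One-row tibble: `peak_hr_mean`, `peak_hr_sd` (sample SD, n-1
#'   denominator; 0 with `degenerate = TRUE` for a single recording) and
#'   `n`.
#' @export
summarize_peaks <- function(peaks) {
  if (nrow(peaks) == 0) abort("No peaks to summarise.")
  v <- peaks$hr_at_peak
  tibble::tibble(
    peak_hr_mean = mean(v),
    peak_hr_sd = if (length(v) > 1) sd(v) else 0,
    n = length(v),
    degenerate = length(v) < 2
  )
}

#' Recording-duration summary
#'
#' A recording's duration is the span of its HR timestamps (last minus
#' first), in minutes; a single-sample recording has duration 0.
#'
#' @param cohort A `"pa_cohort"`.
#' @return One-row tibble: `duration_mean_min`, `duration_sd_min`, `n`.
#' @export
summarize_durations <- function(cohort) {
  if (n_recordings(cohort) == 0) abort("Empty cohort.")
  d <- cohort$samples |>
    dplyr::filter(.data$channel == "hr") |>
    dplyr::group_by(.data$user_id, .data$attack_index) |>
    dplyr::summarise(
      duration_min = (max(.data$t_seconds) - min(.data$t_seconds)) / 60,
      .groups = "drop"
    )
  tibble::tibble(
    duration_mean_min = mean(d$duration_min),
    duration_sd_min = if (nrow(d) > 1) sd(d$duration_min) else 0,
    n = nrow(d)
  )
}

#' Mean lifestyle-contributor ratings
#'
#' Per-factor mean of the 1--5 ordinal codes (3 = typical) over recordings
#' reporting that factor; factors never reported are omitted.
#'
#' @param cohort A `"pa_cohort"`.
#' @return Tibble with columns `factor`, `mean_rating`, `n`.
#' @export
lifestyle_summary <- function(cohort) {
  m <- cohort$meta
  present <- intersect(pa_lifestyle_factors, names(m))
  out <- purrr::map(present, function(f) {
    v <- m[[f]][!is.na(m[[f]])]
    if (length(v) == 0) return(NULL)
    tibble::tibble(factor = f, mean_rating = mean(v), n = length(v))
  })
  purrr::list_rbind(purrr::compact(out))
}

#' Trigger frequencies
#'
#' Counts and proportions of reported attack triggers; recordings without
#' a trigger are excluded from the denominator, so proportions sum to 1
#' over reporting recordings.
#'
#' @param cohort A `"pa_cohort"`.
#' @return Tibble with columns `trigger`, `count`, `proportion`, sorted by
#'   decreasing count (empty if no recording reports a trigger).
#' @export
trigger_frequencies <- function(cohort) {
  tr <- cohort$meta$trigger
  tr <- tr[!is.na(tr)]
  if (length(tr) == 0) {
    return(tibble::tibble(trigger = character(), count = integer(),
                          proportion = numeric()))
  }
  tibble::tibble(trigger = tr) |>
    dplyr::count(.data$trigger, name = "count") |>
    dplyr::mutate(proportion = .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count))
}

#' Full cohort summary
#'
#' One-stop summary of a cohort of attack recordings: runs the inclusion
#' filter, computes the HR ensemble profile through the full alignment /
#' smoothing / partial-coverage pipeline, and derives all cohort-level
#' statistics: peak HR mean and SD, recording duration, ensemble recovery
#' time to the threshold, ensemble peak-to-plateau amplitude, median
#' prominent-cycle count, pooled anxiety recovery slope, lifestyle means
#' and trigger frequencies.
#'
#' @param cohort A `"pa_cohort"` (unfiltered; QC is applied internally).
#' @param recovery_threshold_bpm Recovery threshold (default 85 bpm).
#' @param plateau_window_s Length-2 window (s) over which the
#'   post-recovery plateau level is averaged (default 40--60 s).
#' @param ... Passed to [qc_filter()] (`min_hr_samples`,
#'   `prominence_bpm`).
#' @return A list of class `"pa_cohort_summary"`; supports [tidy()] (long
#'   tibble of statistics) and [glance()] (one-row tibble).
#' @examples
#' cohort <- generate_cohort(generator_config(n_recordings = 40, seed = 3))
#' summary <- cohort_summary(cohort)
#' tidy(summary)
#' @export
cohort_summary <- function(cohort, recovery_threshold_bpm = 85,
                           plateau_window_s = c(40, 60), ...) {
  qc <- qc_filter(cohort, ...)
  prof <- profile_cohort(qc)
  plateau <- mean(prof$mean[prof$t >= plateau_window_s[1] &
                              prof$t <= plateau_window_s[2]], na.rm = TRUE)
  at_peak <- prof$mean[which.min(abs(prof$t))]
  hr_series <- cohort_series(qc$included, "hr")
  cycles <- purrr::map_int(hr_series$samples, count_cycles)
  slope <- tryCatch(anxiety_slope(qc$included, qc$peaks),
                    error = function(e) NULL)
  out <- list(
    report = qc$report,
    peaks = summarize_peaks(qc$peaks),
    durations = summarize_durations(qc$included),
    recovery_time_s = recovery_time(prof, recovery_threshold_bpm),
    ensemble_amplitude_bpm = at_peak - plateau,
    cycles_median = median(cycles),
    anxiety_slope = slope,
    lifestyle = lifestyle_summary(qc$included),
    triggers = trigger_frequencies(qc$included),
    profile = prof
  )
  class(out) <- "pa_cohort_summary"
  out
}

#' @export
print.pa_cohort_summary <- function(x, ...) {
  r <- x$report
  cat("<pa_cohort_summary>\n")
  cat(sprintf("  inclusion: %d/%d recordings (%.1f%% short, %.1f%% no peak)\n",
              r$n_included, r$n_total, r$frac_rejected_short,
              r$frac_rejected_no_peak))
  cat(sprintf("  peak HR: %.1f (SD %.2f) bpm over %d recordings\n",
              x$peaks$peak_hr_mean, x$peaks$peak_hr_sd, x$peaks$n))
  cat(sprintf("  recording duration: %.2f (SD %.2f) min\n",
              x$durations$duration_mean_min, x$durations$duration_sd_min))
  cat(sprintf("  ensemble amplitude: %.1f bpm; recovery to threshold: %s s\n",
              x$ensemble_amplitude_bpm,
              if (is.na(x$recovery_time_s)) "not reached"
              else sprintf("%.1f", x$recovery_time_s)))
  cat(sprintf("  median prominent cycles: %.0f\n", x$cycles_median))
  if (!is.null(x$anxiety_slope)) {
    cat(sprintf("  anxiety slope: %.3f rating/min (SE %.4f)\n",
                x$anxiety_slope$slope, x$anxiety_slope$se))
  }
  invisible(x)
}

#' @rdname cohort_summary
#' @param x A `"pa_cohort_summary"`.
#' @param ... Unused.
#' @export
tidy.pa_cohort_summary <- function(x, ...) {
  base <- tibble::tribble(
    ~statistic, ~value,
    "n_included", as.numeric(x$report$n_included),
    "peak_hr_mean_bpm", x$peaks$peak_hr_mean,
    "peak_hr_sd_bpm", x$peaks$peak_hr_sd,
    "duration_mean_min", x$durations$duration_mean_min,
    "duration_sd_min", x$durations$duration_sd_min,
    "recovery_time_s", x$recovery_time_s,
    "ensemble_amplitude_bpm", x$ensemble_amplitude_bpm,
    "cycles_median", as.numeric(x$cycles_median)
  )
  if (!is.null(x$anxiety_slope)) {
    base <- dplyr::bind_rows(base, tibble::tibble(
      statistic = c("anxiety_slope_per_min", "anxiety_slope_se"),
      value = c(x$anxiety_slope$slope, x$anxiety_slope$se)
    ))
  }
  base
}

#' @rdname cohort_summary
#' @export
glance.pa_cohort_summary <- function(x, ...) {
  tidy(x) |> tidyr::pivot_wider(names_from = "statistic",
                                values_from = "value")
}
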