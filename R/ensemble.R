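#' Partial-coverage ensemble average of gridded series
#'
#' Pointwise mean over exactly those series whose coverage mask is true at
#' each grid point: a series recorded only over part of the window
#' contributes only there. For example, a series with (peak-relative)
#' samples at -17, -5, 0, 20 and 33 s contributes to the ensemble only on
#' the subinterval -15 to 33 s. The number of contributing series is
#' reported per grid point.
#'
#' @param series_list A non-empty list of `"pa_gridded"` objects on the
#'   same grid.
#' @param channel Optional label (`"hr"` or `"anxiety"`) stored on the
#'   result and used for plot annotation.
#' @return A `"pa_profile"` tibble with columns `t`, `mean` (NA where no
#'   series contributes) and `n` (contributing-series count).
#' @export
ensemble_average <- function(series_list, channel = NULL) {
  if (length(series_list) == 0) {
    abort("`series_list` must contain at least one series.")
  }
  grid_t <- series_list[[1]]$t
  same_grid <- purrr::every(series_list, function(s) {
    length(s$t) == length(grid_t) && isTRUE(all.equal(s$t, grid_t))
  })
  if (!same_grid) {
    abort("All series must share the same grid.")
  }
  acc <- numeric(length(grid_t))
  cnt <- integer(length(grid_t))
  for (s in series_list) {
    m <- s$mask & !is.na(s$value)
    acc[m] <- acc[m] + s$value[m]
    cnt[m] <- cnt[m] + 1L
  }
  if (all(cnt == 0L)) {
    abort("All coverage masks are empty; nothing to average.")
  }
  mean_v <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  structure(tibble::tibble(t = grid_t, mean = mean_v, n = cnt),
            class = c("pa_profile", class(tibble::tibble())),
            channel = channel)
}

#' Time for the ensemble profile to recover to a threshold
#'
#' Smallest t >= 0 at which the profile mean first falls to
#' `threshold_bpm`, linearly interpolated between grid points. Returns 0
#' when the profile is already at or below the threshold at the peak, and
#' `NA` when the threshold is never reached within the covered window.
#'
#' @param profile A `"pa_profile"` defined at t = 0.
#' @param threshold_bpm Recovery threshold (default 85 bpm).
#' @return Seconds after the aligned peak, or `NA_real_`.
#' @export
recovery_time <- function(profile, threshold_bpm = 85) {
  post <- profile[profile$t >= 0 & !is.na(profile$mean), ]
  if (nrow(post) == 0 || post$t[1] > 1e-9) {
    abort("Profile must be defined at t = 0.")
  }
  m <- post$mean
  tt <- post$t
  below <- which(m <= threshold_bpm)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(0)
  # linear interpolation of the crossing within the preceding grid step
  frac <- (m[i - 1] - threshold_bpm) / (m[i - 1] - m[i])
  tt[i - 1] + frac * (tt[i] - tt[i - 1])
}

#' Full ensemble-profile pipeline for a cohort
#'
#' Runs the complete profiling chain on an already QC-filtered cohort:
#' align each recording to its first HR peak, interpolate onto the uniform
#' grid, smooth with the zero-phase Butterworth filter, and compute the
#' partial-coverage ensemble average. Anxiety series are aligned by the
#' same recording's HR peak and processed identically; recordings whose
#' chosen channel has no samples inside the window simply contribute
#' nowhere.
#'
#' @param qc A `"pa_qc"` from [qc_filter()], or a `"pa_cohort"` (which is
#'   QC-filtered first with default settings).
#' @param channel `"hr"` or `"anxiety"`.
#' @param window,dt Grid specification passed to [align_and_grid()].
#' @param order,cutoff_hz Filter specification passed to
#'   [smooth_series()].
#' @param smooth Set FALSE to skip the smoothing stage.
#' @return A `"pa_profile"`; attributes `report` and `peaks` carry the QC
#'   report and the per-recording peak locations, and `series` the list of
#'   smoothed `"pa_gridded"` series entering the average.
#' @examples
#' cohort <- generate_cohort(generator_config(n_recordings = 30, seed = 1))
#' prof <- profile_cohort(cohort)
#' recovery_time(prof)
#' @export
profile_cohort <- function(qc, channel = c("hr", "anxiety"),
                           window = c(-15, 60), dt = 0.01,
                           order = 4, cutoff_hz = 0.1, smooth = TRUE) {
  channel <- match.arg(channel)
  if (inherits(qc, "pa_cohort")) qc <- qc_filter(qc)
  series <- gridded_series_list(qc, channel, window = window, dt = dt,
                                order = order, cutoff_hz = cutoff_hz,
                                smooth = smooth)
  prof <- ensemble_average(series, channel = channel)
  attr(prof, "report") <- qc$report
  attr(prof, "peaks") <- qc$peaks
  attr(prof, "series") <- series
  prof
}

gridded_series_list <- function(qc, channel, window = c(-15, 60), dt = 0.01,
                                order = 4, cutoff_hz = 0.1, smooth = TRUE) {
  nested <- cohort_series(qc$included, channel) |>
    dplyr::inner_join(qc$peaks, by = c("user_id", "attack_index"))
  out <- purrr::map2(nested$samples, nested$t_seconds, function(s, pk) {
    g <- align_and_grid(s, pk, window = window, dt = dt)
    if (smooth && any(g$mask)) {
      g <- suppressWarnings(smooth_series(g, order = order,
                                          cutoff_hz = cutoff_hz))
    }
    g
  })
  purrr::keep(out, function(g) any(g$mask))
}
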