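new_gridded <- function(t, value, mask) {
  structure(tibble::tibble(t = t, value = value, mask = mask),
            class = c("pa_gridded", class(tibble::tibble())))
}

#' Align a sparse series to its HR peak and interpolate onto a uniform grid
#'
#' Shifts timestamps so the recording's first HR peak sits at t = 0, then
#' linearly interpolates the samples onto a uniform grid (default 0.01 s
#' steps over -15 to 60 s around the peak). No extrapolation is performed:
#' the coverage mask is true exactly on the single contiguous interval
#' `[max(window[1], first shifted timestamp), min(window[2], last shifted
#' timestamp)]`, and values are defined only there. A series lying entirely
#' outside the window yields an all-false mask. Anxiety series are aligned
#' by the same recording's HR peak (no separate anxiety peak detection).
#'
#' @param samples A data frame with columns `t_seconds` and `value`.
#' @param peak_t_seconds Timestamp (s, recording clock) of the first HR
#'   peak, e.g. `detect_first_peak(s)$t_seconds`.
#' @param window Length-2 peak-relative window in seconds (default
#'   `c(-15, 60)`).
#' @param dt Grid step in seconds (default 0.01); both window endpoints are
#'   included in the grid.
#' @return A `"pa_gridded"` tibble with columns `t` (peak-relative
#'   seconds), `value` (NA outside coverage) and `mask`.
#' @examples
#' s <- tibble::tibble(t_seconds = c(-17, -5, 0, 20, 33) + 100,
#'                     value = c(80, 90, 98, 88, 84))
#' g <- align_and_grid(s, peak_t_seconds = 100)
#' range(g$t[g$mask])  # coverage exactly [-15, 33]
#' @export
align_and_grid <- function(samples, peak_t_seconds, window = c(-15, 60),
                           dt = 0.01) {
  grid_t <- seq(window[1], window[2], by = dt)
  ts <- samples$t_seconds - peak_t_seconds
  v <- samples$value
  eps <- dt * 1e-6
  lo <- max(window[1], min(ts))
  hi <- min(window[2], max(ts))
  mask <- grid_t >= lo - eps & grid_t <= hi + eps
  value <- rep(NA_real_, length(grid_t))
  if (any(mask)) {
    if (length(ts) >= 2) {
      value[mask] <- approx(ts, v, xout = grid_t[mask], rule = 1)$y
      # guard against NA at the support edges from floating-point overshoot
      value[mask][is.na(value[mask])] <-
        approx(ts, v, xout = pmin(pmax(grid_t[mask][is.na(value[mask])],
                                       min(ts)), max(ts)))$y
    } else {
      value[mask] <- v
    }
  }
  new_gridded(grid_t, value, mask)
}

# Steady-state forward-backward Butterworth pass over one contiguous
# segment, with odd-reflection padding at both ends.
filtfilt_steady <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  xp <- if (pad > 0) {
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else {
    x
  }
  nb <- length(b) - 1
  na_ <- length(a) - 1
  one_pass <- function(z) {
    signal::filter(b, a, z, init.x = rep(z[1], nb), init.y = rep(z[1], na_))
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Zero-phase Butterworth smoothing of a gridded series
#'
#' Applies a low-pass Butterworth filter (default 4th order, 0.1 Hz cutoff
#' at the grid's sampling rate) forward and backward over the masked
#' support, so the result has no phase lag (peaks are not shifted in
#' time). The support is padded by odd reflection (up to 3 characteristic
#' lengths, `3 / cutoff_hz` seconds) and each filter pass starts from the
#' steady state of the segment's first value, so constants pass through
#' exactly and edge transients are negligible. The two passes square the
#' magnitude response: `|H(f)|^2 = (1 + (f / fc)^(2 * order))^-1` per pass.
#' The mask is never altered.
#'
#' @param series A `"pa_gridded"` from [align_and_grid()] (any uniform
#'   grid is accepted).
#' @param order Butterworth prototype order (default 4).
#' @param cutoff_hz Cutoff frequency in Hz (default 0.1); must be below
#'   the grid Nyquist frequency.
#' @param min_support_s Supports shorter than this (default 1 s) are
#'   returned unchanged with a warning, as too short to filter stably.
#' @return The smoothed `"pa_gridded"`; attribute `smoothed` is TRUE when
#'   the filter was applied.
#' @export
smooth_series <- function(series, order = 4, cutoff_hz = 0.1,
                          min_support_s = 1) {
  dt <- series$t[2] - series$t[1]
  fs <- 1 / dt
  if (cutoff_hz >= fs / 2) {
    abort("`cutoff_hz` must be below the grid Nyquist frequency.")
  }
  idx <- which(series$mask)
  if (length(idx) * dt < min_support_s || length(idx) < 3 * (order + 1)) {
    warn("Masked support too short to smooth; returning the series unchanged.")
    attr(series, "smoothed") <- FALSE
    return(series)
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  pad <- round(3 * fs / cutoff_hz)
  out <- series
  out$value[idx] <- filtfilt_steady(bf$b, bf$a, series$value[idx], pad)
  attr(out, "smoothed") <- TRUE
  out
}

#' Remove the support mean of a gridded series
#'
#' Subtracts the mean over the masked support, the form in which
#' individual HR traces are overlaid to show heterogeneity around the
#' ensemble profile.
#'
#' @param series A `"pa_gridded"`.
#' @return The demeaned `"pa_gridded"` (mean over support is 0).
#' @export
demean_series <- function(series) {
  idx <- which(series$mask)
  if (length(idx) == 0) {
    abort("Cannot demean a series with empty support.")
  }
  series$value[idx] <- series$value[idx] - mean(series$value[idx])
  series
}
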