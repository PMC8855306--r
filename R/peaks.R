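#' Detect the first clear peak of a sparse HR series
#'
#' The alignment anchor for ensemble averaging is the first "clear" peak of
#' the raw HR samples: the earliest interior sample strictly greater than
#' both neighbours whose value exceeds the minimum of all preceding samples
#' by at least `prominence_bpm`. The prominence requirement makes the
#' anchor robust to 1--2 bpm measurement jitter while accepting the
#' ~15 bpm excursions typical of a panic attack.
#'
#' @param samples A data frame with columns `t_seconds` and `value`
#'   (bpm), sorted by time.
#' @param prominence_bpm Minimum rise (bpm) over the preceding minimum.
#' @return A one-row tibble with `index`, `t_seconds`, `hr_at_peak`, or
#'   `NULL` if no qualifying peak exists (including series with fewer than
#'   3 samples, which cannot contain an interior peak).
#' @examples
#' s <- tibble::tibble(t_seconds = c(0, 20, 40, 60),
#'                     value = c(70, 92, 75, 72))
#' detect_first_peak(s)  # peak at t = 20 s, 92 bpm
#' @export
detect_first_peak <- function(samples, prominence_bpm = 5) {
  v <- samples$value
  n <- length(v)
  if (n < 3) return(NULL)
  interior <- 2:(n - 1)
  is_max <- v[interior] > v[interior - 1] & v[interior] > v[interior + 1]
  run_min <- cummin(v)
  prominent <- v[interior] - run_min[interior - 1] >= prominence_bpm
  hits <- interior[is_max & prominent]
  if (length(hits) == 0) return(NULL)
  i <- hits[1]
  tibble::tibble(index = i, t_seconds = samples$t_seconds[i],
                 hr_at_peak = v[i])
}

# Topographic prominence of a local maximum: height above the higher of
# the two bracketing minima, where each bracket extends until a strictly
# higher sample (or the series end) is met.
peak_prominences <- function(v, idx) {
  purrr::map_dbl(idx, function(i) {
    h <- v[i]
    j <- i - 1
    left_min <- h
    while (j >= 1 && v[j] <= h) {
      left_min <- min(left_min, v[j])
      j <- j - 1
    }
    k <- i + 1
    right_min <- h
    n <- length(v)
    while (k <= n && v[k] <= h) {
      right_min <- min(right_min, v[k])
      k <- k + 1
    }
    h - max(left_min, right_min)
  })
}

#' Count prominent HR arousal cycles in a recording
#'
#' Counts interior local maxima of the HR series whose topographic
#' prominence (height above the higher of the two bracketing minima) is at
#' least `prominence_bpm`, keeping at most one peak per
#' `min_separation_s`-wide neighbourhood (higher peaks win). Arousal cycles
#' are slow (minutes apart), so the same frequency criterion used for
#' profiling applies here: when the sampling is dense enough to resolve
#' the `cutoff_hz` low-pass band (median inter-sample interval below
#' `1 / (4 * cutoff_hz)`), the series is first interpolated onto a uniform
#' grid and zero-phase Butterworth filtered, so sub-second measurement
#' noise is not counted as cycling. Sparser series are counted as-is
#' (sparse sampling cannot alias noise into the cycle band).
#'
#' @param samples A data frame with columns `t_seconds` and `value` (bpm).
#' @param prominence_bpm Minimum prominence (bpm) for a countable cycle.
#' @param min_separation_s Minimum spacing (s) between counted cycle
#'   apexes.
#' @param cutoff_hz Low-pass cutoff applied to densely sampled series
#'   before counting (default 0.1 Hz, matching [smooth_series()]); set to
#'   `NA` to count raw samples unconditionally.
#' @return Integer cycle count (0 for series with fewer than 3 samples).
#' @export
count_cycles <- function(samples, prominence_bpm = 5, min_separation_s = 30,
                         cutoff_hz = 0.1) {
  v <- samples$value
  tt <- samples$t_seconds
  n <- length(v)
  if (n < 3) return(0L)
  dt_med <- median(diff(tt))
  if (!is.na(cutoff_hz) && dt_med <= 1 / (4 * cutoff_hz) && n >= 16) {
    grid <- seq(min(tt), max(tt), by = dt_med)
    vg <- approx(tt, v, xout = grid)$y
    bf <- signal::butter(4, cutoff_hz / (0.5 / dt_med), type = "low")
    pad <- round(3 / (cutoff_hz * dt_med))
    vg <- filtfilt_steady(bf$b, bf$a, vg, pad)
    tt <- grid
    v <- vg
    n <- length(v)
  }
  interior <- 2:(n - 1)
  idx <- interior[v[interior] > v[interior - 1] & v[interior] > v[interior + 1]]
  if (length(idx) == 0) return(0L)
  prom <- peak_prominences(v, idx)
  idx <- idx[prom >= prominence_bpm]
  if (length(idx) == 0) return(0L)
  # greedy suppression: keep the highest peak, drop neighbours within the
  # separation window, repeat
  ord <- idx[order(v[idx], decreasing = TRUE)]
  kept <- numeric(0)
  for (i in ord) {
    if (all(abs(tt[i] - kept) >= min_separation_s)) {
      kept <- c(kept, tt[i])
    }
  }
  length(kept)
}
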