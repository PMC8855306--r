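#' Inclusion filter for panic-attack recordings
#'
#' Applies the two inclusion criteria for profile analysis, in order: a
#' recording must have at least `min_hr_samples` HR samples (otherwise it
#' is rejected as "short"), and its HR series must contain a clear first
#' peak per [detect_first_peak()] (otherwise rejected as "no peak").
#' Checking the sample-count rule first makes the report buckets disjoint:
#' every recording lands in exactly one of short / no-peak / included.
#'
#' @param cohort A `"pa_cohort"` (must be non-empty).
#' @param min_hr_samples Minimum number of HR samples (default 4).
#' @param prominence_bpm Peak prominence passed to [detect_first_peak()].
#' @return A list of class `"pa_qc"` with elements:
#'   \describe{
#'     \item{included}{`"pa_cohort"` of recordings passing both rules.}
#'     \item{report}{One-row tibble: `n_total`, `n_rejected_short`,
#'       `n_rejected_no_peak`, `n_included`, and the rejection percentages
#'       `frac_rejected_short` / `frac_rejected_no_peak` (half-up, 1
#'       decimal).}
#'     \item{peaks}{Tibble of detected first peaks for the included
#'       recordings (`user_id`, `attack_index`, `index`, `t_seconds`,
#'       `hr_at_peak`).}
#'   }
#' @examples
#' fx <- make_fixture_cohort(148, 80, 18, seed = 7)
#' qc_filter(fx)$report
#' @export
qc_filter <- function(cohort, min_hr_samples = 4, prominence_bpm = 5) {
  if (n_recordings(cohort) == 0) {
    abort("Cannot QC-filter an empty cohort.")
  }
  hr <- cohort_series(cohort, "hr")
  # recordings with no HR rows at all still count as "short"
  hr <- dplyr::full_join(
    dplyr::select(cohort$meta, "user_id", "attack_index"), hr,
    by = c("user_id", "attack_index")
  )
  hr <- hr |>
    dplyr::mutate(
      n_hr = purrr::map_int(.data$samples,
                            function(s) if (is.null(s)) 0L else nrow(s)),
      peak = purrr::map(.data$samples, function(s) {
        if (is.null(s)) NULL else detect_first_peak(s, prominence_bpm)
      }),
      status = dplyr::case_when(
        .data$n_hr < min_hr_samples ~ "short",
        purrr::map_lgl(.data$peak, is.null) ~ "no_peak",
        TRUE ~ "included"
      )
    )
  n_total <- nrow(hr)
  n_short <- sum(hr$status == "short")
  n_nopeak <- sum(hr$status == "no_peak")
  report <- tibble::tibble(
    n_total = n_total,
    n_rejected_short = n_short,
    n_rejected_no_peak = n_nopeak,
    n_included = n_total - n_short - n_nopeak,
    frac_rejected_short = percent(n_short, n_total, 1),
    frac_rejected_no_peak = percent(n_nopeak, n_total, 1)
  )
  inc <- dplyr::filter(hr, .data$status == "included")
  peaks <- inc |>
    dplyr::mutate(peak = purrr::map(.data$peak, tibble::as_tibble)) |>
    dplyr::select("user_id", "attack_index", "peak") |>
    tidyr::unnest("peak")
  included <- subset_cohort(cohort, inc[c("user_id", "attack_index")])
  structure(list(included = included, report = report, peaks = peaks),
            class = "pa_qc")
}

#' @export
print.pa_qc <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<pa_qc> %d recordings: %d rejected short (%.1f%%), %d rejected no-peak (%.1f%%), %d included\n",
    r$n_total, r$n_rejected_short, r$frac_rejected_short,
    r$n_rejected_no_peak, r$frac_rejected_no_peak, r$n_included))
  invisible(x)
}
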