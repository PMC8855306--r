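#' Plot an ensemble profile
#'
#' Line plot of the ensemble mean on the peak-relative time axis, with a
#' lighter band showing how many series contribute at each instant
#' (partial coverage makes the tails thinner than the centre).
#'
#' @param object A `"pa_profile"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pa_profile <- function(object, ...) {
  channel <- attr(object, "channel") %||% "hr"
  ylab <- if (identical(channel, "anxiety")) "Anxiety rating (0-10)"
          else "Heart rate (bpm)"
  df <- object[!is.na(object$mean), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mean)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "Time relative to first HR peak (s)", y = ylab,
      subtitle = sprintf("Partial-coverage ensemble of up to %d series",
                         max(object$n))
    ) +
    ggplot2::theme_minimal()
}

#' Plot demeaned individual traces under the ensemble mean
#'
#' Overlays the demeaned, smoothed per-recording traces (grey) with the
#' ensemble average of the raw (non-demeaned) traces re-centred for
#' comparison (black), showing the heterogeneity around the mean profile.
#'
#' @param profile A `"pa_profile"` from [profile_cohort()] (which carries
#'   the per-recording gridded series as an attribute).
#' @return A ggplot.
#' @export
plot_demeaned_traces <- function(profile) {
  series <- attr(profile, "series")
  if (is.null(series)) {
    abort("`profile` carries no per-recording series; use profile_cohort().")
  }
  traces <- purrr::imap(series, function(s, i) {
    d <- demean_series(s)
    tibble::tibble(id = i, t = d$t[d$mask], value = d$value[d$mask])
  }) |> purrr::list_rbind()
  em <- profile[!is.na(profile$mean), ]
  em$centered <- em$mean - mean(em$mean)
  ggplot2::ggplot(traces,
                  ggplot2::aes(x = .data$t, y = .data$value,
                               group = .data$id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_line(data = em,
                       ggplot2::aes(y = .data$centered, group = NULL),
                       colour = "black", linewidth = 0.9) +
    ggplot2::labs(x = "Time relative to first HR peak (s)",
                  y = "Demeaned heart rate (bpm)") +
    ggplot2::theme_minimal()
}

#' Plot the raw recordings of a cohort
#'
#' Spaghetti plot of the sparse raw samples per recording, faceted by
#' channel; useful for eyeballing generated or ingested data before QC.
#'
#' @param object A `"pa_cohort"`.
#' @param max_recordings Cap on the number of recordings drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pa_cohort <- function(object, max_recordings = 30, ...) {
  keep <- head(object$meta[c("user_id", "attack_index")], max_recordings)
  df <- dplyr::semi_join(object$samples, keep,
                         by = c("user_id", "attack_index"))
  df$rec <- paste(df$user_id, df$attack_index)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_seconds, y = .data$value,
                                   group = .data$rec)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::facet_wrap(~ .data$channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time since recording start (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pa_slope_fit <- function(object, ...) {
  df <- object$model$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$value)) +
    ggplot2::geom_jitter(alpha = 0.3, width = 0, height = 0.15) +
    ggplot2::geom_abline(intercept = coef(object$model)[1],
                         slope = object$slope, colour = "red") +
    ggplot2::labs(x = "Minutes since first HR peak",
                  y = "Anxiety rating (0-10)") +
    ggplot2::theme_minimal()
}
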