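# Latent attack trajectory: baseline plus a train of raised-cosine arousal
# bumps. Compact support keeps inter-cycle segments exactly at baseline and
# the 4/3 * recovery_tau half-width puts the ensemble's crossing of the
# 85 bpm threshold near recovery_tau seconds after the apex under defaults.
latent_hr <- function(t, baseline, amps, centers, half_width) {
  v <- rep(baseline, length(t))
  for (k in seq_along(centers)) {
    u <- (t - centers[k]) / half_width
    inside <- abs(u) < 1
    v[inside] <- v[inside] + amps[k] * (1 + cos(pi * u[inside])) / 2
  }
  v
}

# Gamma-distributed inter-sample gaps (shape 4 => CV 0.5) around the app's
# mean prompt cycle; first sample lands uniformly within one mean interval.
sample_times <- function(total_s, mean_interval, shape = 4) {
  n_max <- ceiling(total_s / mean_interval * 3) + 10
  gaps <- rgamma(n_max, shape = shape, scale = mean_interval / shape)
  tt <- cumsum(c(runif(1, 0, mean_interval), gaps))
  tt[tt <= total_s]
}

# Log-normal recording duration moment-matched to (mean, sd) minutes, then
# rejection-sampled into the truncation range (SD > mean rules out a
# symmetric law).
draw_duration_min <- function(cfg) {
  s2 <- log(1 + (cfg$duration_sd_min / cfg$duration_mean_min)^2)
  mu <- log(cfg$duration_mean_min) - s2 / 2
  lo <- cfg$duration_range_min[1]
  hi <- cfg$duration_range_min[2]
  repeat {
    d <- rlnorm(1, meanlog = mu, sdlog = sqrt(s2))
    if (d >= lo && d <= hi) return(d)
  }
}

# Arousal amplitude conditional on the attack's peak HR: Normal around the
# configured mean excursion, truncated at 6 bpm so every well-formed attack
# has a detectable peak. Drawing peak first keeps its law exact.
draw_amplitude <- function(cfg) {
  mu <- cfg$peak_hr_mean - cfg$baseline_hr_mean
  if (cfg$baseline_hr_sd == 0) return(mu)
  floor_a <- min(6, mu)
  repeat {
    a <- rnorm(1, mu, cfg$baseline_hr_sd)
    if (a >= floor_a) return(a)
  }
}

simulate_recording <- function(cfg, type) {
  d_s <- 60 * draw_duration_min(cfg)
  peak <- rnorm(1, cfg$peak_hr_mean, cfg$peak_hr_sd)
  amp <- draw_amplitude(cfg)
  baseline <- max(peak - amp, 30)
  period <- cfg$cycle_period_s * runif(1, 0.9, 1.1)
  # Bump half-width calibrated so the default full-pipeline ensemble (which
  # widens each aligned bump by sampling jitter around the apex and by the
  # 0.1 Hz zero-phase smoothing) first crosses the 85 bpm recovery
  # threshold about recovery_tau_s seconds after the peak.
  half_width <- min(1.1 * cfg$recovery_tau_s, 0.45 * period)
  t0 <- runif(1, cfg$peak_time_range_s[1], cfg$peak_time_range_s[2])
  # "approximately n_cycles_mean cycles per attack": concentrated, SD 1
  n_cyc <- max(1L, as.integer(round(rnorm(1, cfg$n_cycles_mean, 1))))
  centers <- t0 + (seq_len(n_cyc) - 1) * period
  amps <- amp * cfg$cycle_decay^(seq_len(n_cyc) - 1)

  t_offset <- 0
  if (type == "no_peak") {
    # App opened after the attack's HR apex: only the decaying limb of the
    # first cycle is sampled (>= 4 samples so the short-recording rule does
    # not fire first). The recording clock starts at the first sample.
    m <- sample(4:6, 1)
    tt_hr <- t0 + 2 + (seq_len(m) - 1) * (half_width - 4) / (m - 1) +
      runif(m, -1, 1)
    tt_hr <- sort(tt_hr)
    t_offset <- tt_hr[1]
    d_s <- min(d_s, max(tt_hr) - t_offset + cfg$hr_sample_interval_s)
  } else {
    tt_hr <- sample_times(d_s, cfg$hr_sample_interval_s)
    if (length(tt_hr) == 0) tt_hr <- runif(1, 0, d_s)
    if (type == "too_short") {
      # App terminated early: keep only the first 1-3 HR samples.
      k <- sample(1:3, 1)
      tt_hr <- head(tt_hr, k)
    }
  }
  hr <- latent_hr(tt_hr, baseline, amps, centers, half_width) +
    rnorm(length(tt_hr), 0, cfg$hr_noise_sd)
  hr <- pmax(hr, 30)

  a0 <- sample(seq(cfg$anxiety_start_range[1], cfg$anxiety_start_range[2]), 1)
  anx_end <- if (type == "too_short") max(tt_hr) else t_offset + d_s
  # Anxiety prompting stops after a cohort-constant window: the time at
  # which the lowest configured starting rating would decline to 1. This
  # keeps the linear model valid over the whole observed window (ratings
  # never pile up at the scale floor) and, because the cap does not depend
  # on the recording's own starting rating, the observation window is not
  # informative about the intercept, so pooled OLS stays unbiased.
  if (cfg$anxiety_slope_per_min < 0) {
    t_floor <- 60 * (cfg$anxiety_start_range[1] - 1) /
      -cfg$anxiety_slope_per_min
    anx_end <- min(anx_end, t_floor)
  }
  tt_anx <- t_offset + sample_times(max(anx_end - t_offset, 1),
                                    cfg$anxiety_sample_interval_s)
  anx <- a0 + cfg$anxiety_slope_per_min * tt_anx / 60 +
    rnorm(length(tt_anx), 0, cfg$anxiety_noise_sd)
  anx <- pmin(pmax(round(anx), 0), 10)

  lifestyle <- pmin(pmax(round(rnorm(
    length(pa_lifestyle_factors),
    cfg$lifestyle_means[pa_lifestyle_factors], 1)), 1), 5)
  names(lifestyle) <- pa_lifestyle_factors
  trigger <- sample(names(cfg$trigger_weights), 1,
                    prob = cfg$trigger_weights)

  list(
    hr = tibble::tibble(t_seconds = tt_hr - t_offset, value = hr),
    anxiety = tibble::tibble(t_seconds = tt_anx - t_offset, value = anx),
    lifestyle = lifestyle, trigger = trigger, type = type
  )
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

#' Generate a synthetic cohort of panic-attack recordings
#'
#' Simulates `config$n_recordings` app-recorded attacks. Each attack has a
#' latent HR trajectory (baseline plus a decaying train of raised-cosine
#' arousal bumps), sampled sparsely at jittered intervals with Gaussian
#' measurement noise, and an anxiety rating series declining linearly at
#' the configured slope, rounded to integers and clipped to 0--10. With the
#' configured probabilities a recording instead exhibits one of the two
#' observed failure modes: termination before 4 HR samples were collected,
#' or a start after the attack's HR apex (no interior peak in the samples).
#' Identical configurations (including the seed) produce identical cohorts;
#' per-recording sub-seeds are derived from the cohort seed so recordings
#' are individually reproducible. The caller's RNG state is left untouched.
#'
#' @param config A [generator_config()].
#' @return A `"pa_cohort"`; `meta` carries a `failure_mode` column with the
#'   injected condition (`"none"`, `"too_short"` or `"no_peak"`) for use in
#'   calibration checks (a QC filter on real data has no such column).
#' @examples
#' cohort <- generate_cohort(generator_config(n_recordings = 20, seed = 42))
#' cohort
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  with_preserved_rng({
    set.seed(config$seed)
    n <- config$n_recordings
    rec_seeds <- sample.int(.Machine$integer.max, n)
    u <- runif(n)
    types <- dplyr::case_when(
      u < config$p_too_short ~ "too_short",
      u < config$p_too_short + config$p_no_peak ~ "no_peak",
      TRUE ~ "none"
    )
    recs <- purrr::map(seq_len(n), function(i) {
      set.seed(rec_seeds[i])
      simulate_recording(config, types[i])
    })
    assemble_cohort(recs, config)
  })
}

assemble_cohort <- function(recs, config) {
  ids <- sprintf("u%04d", seq_along(recs))
  samples <- purrr::imap(recs, function(r, i) {
    dplyr::bind_rows(
      dplyr::mutate(r$hr, channel = "hr"),
      dplyr::mutate(r$anxiety, channel = "anxiety")
    ) |>
      dplyr::mutate(user_id = ids[[i]], attack_index = 1L) |>
      dplyr::select("user_id", "attack_index", "channel", "t_seconds", "value")
  }) |>
    purrr::list_rbind()
  meta <- purrr::imap(recs, function(r, i) {
    tibble::tibble(
      user_id = ids[[i]], attack_index = 1L,
      !!!as.list(r$lifestyle), trigger = r$trigger,
      failure_mode = if (is.null(r$type)) "none" else r$type
    )
  }) |>
    purrr::list_rbind()
  as_pa_cohort(samples, meta, config = config)
}

#' Deterministic fixture cohort with exact failure counts
#'
#' Builds a cohort in which exactly `n_too_short` recordings have fewer
#' than 4 HR samples, exactly `n_no_peak` have at least 4 samples but a
#' strictly monotone (peak-free) HR series, and the remainder are clean
#' attacks with an unambiguous interior peak. Useful for exercising
#' [qc_filter()] against known rejection counts, e.g. a 148-recording
#' cohort with 80 short and 18 peak-free recordings yields exactly 50
#' included.
#'
#' @param n_total Total number of recordings.
#' @param n_too_short Number with < 4 HR samples.
#' @param n_no_peak Number with >= 4 samples but no interior peak.
#' @param seed Integer seed controlling the (otherwise irrelevant) order in
#'   which the three kinds are interleaved.
#' @return A `"pa_cohort"` with a `failure_mode` metadata column.
#' @examples
#' fx <- make_fixture_cohort(148, 80, 18, seed = 7)
#' qc_filter(fx)$report
#' @export
make_fixture_cohort <- function(n_total, n_too_short, n_no_peak, seed = 0L) {
  if (n_too_short + n_no_peak > n_total) {
    abort("`n_too_short` + `n_no_peak` must not exceed `n_total`.")
  }
  with_preserved_rng({
    set.seed(seed)
    types <- sample(c(rep("too_short", n_too_short),
                      rep("no_peak", n_no_peak),
                      rep("none", n_total - n_too_short - n_no_peak)))
    recs <- purrr::map(seq_len(n_total), function(i) {
      fixture_recording(types[[i]], i)
    })
    assemble_cohort(recs, config = NULL)
  })
}

fixture_recording <- function(type, i) {
  if (type == "too_short") {
    k <- 1L + (i %% 3L)
    hr <- tibble::tibble(t_seconds = seq(0, by = 15, length.out = k),
                         value = 84 + seq_len(k))
  } else if (type == "no_peak") {
    # strictly monotone decline: no interior local maximum by construction
    hr <- tibble::tibble(t_seconds = seq(0, 75, by = 15),
                         value = seq(96, 76, length.out = 6))
  } else {
    # clean single-cycle attack, apex exactly on a sample at t = 60 s
    tt <- seq(0, 180, by = 15)
    v <- latent_hr(tt, baseline = 78 + (i %% 4), amps = 16 + (i %% 5),
                   centers = 60, half_width = 40)
    hr <- tibble::tibble(t_seconds = tt, value = v)
  }
  dur <- max(hr$t_seconds)
  tt_anx <- seq(0, max(dur, 1), by = 60)
  anx <- pmin(pmax(round(7 - 0.43 * tt_anx / 60), 0), 10)
  lifestyle <- setNames(1L + ((i + seq_along(pa_lifestyle_factors)) %% 5L),
                        pa_lifestyle_factors)
  list(
    hr = hr,
    anxiety = tibble::tibble(t_seconds = tt_anx, value = anx),
    lifestyle = lifestyle,
    trigger = pa_trigger_levels[1L + (i %% length(pa_trigger_levels))],
    type = type
  )
}
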