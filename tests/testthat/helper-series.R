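# Builders used across test files.

series_tbl <- function(t, v) tibble::tibble(t_seconds = t, value = v)

# gridded series on the default window with given support and values
gridded <- function(values_fn, support = c(-15, 60), window = c(-15, 60),
                    dt = 0.01) {
  t <- seq(window[1], window[2], by = dt)
  mask <- t >= support[1] - 1e-9 & t <= support[2] + 1e-9
  value <- rep(NA_real_, length(t))
  value[mask] <- values_fn(t[mask])
  structure(tibble::tibble(t = t, value = value, mask = mask),
            class = c("pa_gridded", class(tibble::tibble())))
}

# a clean raised-cosine attack sampled every `by` seconds
bump_series <- function(baseline = 80, amp = 18, center = 60, hw = 40,
                        t_end = 180, by = 15) {
  t <- seq(0, t_end, by = by)
  u <- (t - center) / hw
  v <- baseline + ifelse(abs(u) < 1, amp * (1 + cos(pi * u)) / 2, 0)
  series_tbl(t, v)
}

# tiny hand-built cohort: one clean recording + optional extras
tiny_cohort <- function(extra_samples = NULL, extra_meta = NULL) {
  b <- bump_series()
  samples <- dplyr::bind_rows(
    tibble::tibble(user_id = "a", attack_index = 1L, channel = "hr",
                   t_seconds = b$t_seconds, value = b$value),
    tibble::tibble(user_id = "a", attack_index = 1L, channel = "anxiety",
                   t_seconds = c(0, 60, 120), value = c(8, 7, 7)),
    extra_samples
  )
  meta <- dplyr::bind_rows(
    tibble::tibble(user_id = "a", attack_index = 1L,
                   exercise = 3L, sleep = 3L, diet = 3L, stress = 3L,
                   substance_use = 3L, trigger = "health"),
    extra_meta
  )
  as_pa_cohort(samples, meta)
}
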