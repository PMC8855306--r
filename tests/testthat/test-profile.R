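test_that("ensemble averaging honours partial coverage", {
  f <- function(t) 90 + 0.1 * t
  a <- gridded(f, support = c(-15, 20))
  b <- gridded(f, support = c(-15, 20))
  prof <- ensemble_average(list(a, b))
  expect_equal(prof$mean[prof$n > 0], a$value[a$mask])
  expect_true(all(prof$n[a$mask] == 2))
  expect_true(all(prof$n[!a$mask] == 0))
  expect_true(all(is.na(prof$mean[prof$n == 0])))

  # disjoint supports: each series alone on its own stretch
  lo <- gridded(function(t) rep(80, length(t)), support = c(-15, 0))
  hi <- gridded(function(t) rep(100, length(t)), support = c(10, 60))
  prof2 <- ensemble_average(list(lo, hi))
  expect_true(all(prof2$mean[prof2$t <= 0 & prof2$n > 0] == 80))
  expect_true(all(prof2$mean[prof2$t >= 10 & prof2$n > 0] == 100))
  expect_true(all(prof2$n[prof2$n > 0] == 1))

  expect_error(ensemble_average(list()), "at least one")
  none <- gridded(function(t) t, support = c(100, 101))
  expect_error(ensemble_average(list(none)), "empty")
})

test_that("ensemble average is permutation-invariant and bounded by inputs", {
  set.seed(4)
  series <- purrr::map(1:5, function(i) {
    lo <- runif(1, -15, 10); hi <- runif(1, 20, 60)
    off <- rnorm(1, 0, 5)
    gridded(function(t) 90 + off + sin(t / 10), support = c(lo, hi))
  })
  p1 <- ensemble_average(series)
  p2 <- ensemble_average(rev(series))
  expect_equal(p1, p2)

  vals <- sapply(series, function(s) ifelse(s$mask, s$value, NA))
  idx <- which(p1$n > 0)
  lo_b <- apply(vals[idx, , drop = FALSE], 1, min, na.rm = TRUE)
  hi_b <- apply(vals[idx, , drop = FALSE], 1, max, na.rm = TRUE)
  expect_true(all(p1$mean[idx] >= lo_b - 1e-12))
  expect_true(all(p1$mean[idx] <= hi_b + 1e-12))
})

test_that("recovery time interpolates the threshold crossing linearly", {
  lin <- gridded(function(t) ifelse(t < 0, 100, 100 - 0.5 * t))
  prof <- ensemble_average(list(lin))
  expect_equal(recovery_time(prof, 85), 30, tolerance = 1e-6)

  flat <- ensemble_average(list(gridded(function(t) rep(98, length(t)))))
  expect_true(is.na(recovery_time(flat, 85)))

  below <- ensemble_average(list(gridded(function(t) rep(70, length(t)))))
  expect_equal(recovery_time(below, 85), 0)

  # monotone nonincreasing profile: recovery time nonincreasing in threshold
  times <- sapply(c(80, 85, 90, 95), function(th) recovery_time(prof, th))
  expect_true(all(diff(times) <= 0))
})

test_that("cycle counting finds prominent bumps and ignores flat series", {
  expect_equal(count_cycles(bump_series()), 1L)
  expect_equal(count_cycles(series_tbl(seq(0, 100, 10), rep(80, 11))), 0L)
  expect_equal(count_cycles(series_tbl(c(0, 10), c(80, 90))), 0L)

  # four clean cycles at 150 s spacing, decaying amplitude
  t <- seq(0, 600, by = 5)
  v <- 83 + sapply(t, function(x) {
    sum(sapply(0:3, function(k) {
      u <- (x - (40 + k * 150)) / 33
      if (abs(u) < 1) 15 * 0.85^k * (1 + cos(pi * u)) / 2 else 0
    }))
  })
  expect_equal(count_cycles(series_tbl(t, v)), 4L)
  # sub-prominence ripples are not cycles
  ripple <- series_tbl(seq(0, 300, 10), 80 + 2 * sin(seq(0, 300, 10) / 20))
  expect_equal(count_cycles(ripple), 0L)
})

test_that("anxiety slope fits pooled ratings after the HR peak", {
  # three recordings, ratings exactly on the common line 9 - t_min
  mk <- function(id, tmin) {
    tibble::tibble(user_id = id, attack_index = 1L, channel = "anxiety",
                   t_seconds = tmin * 60, value = 9 - tmin)
  }
  hr <- purrr::map(c("a", "b", "c"), function(id) {
    tibble::tibble(user_id = id, attack_index = 1L, channel = "hr",
                   t_seconds = c(-20, 0, 20), value = c(80, 95, 82))
  }) |> purrr::list_rbind()
  samples <- dplyr::bind_rows(hr, mk("a", 0:2), mk("b", 1:3), mk("c", c(0, 4)))
  co <- as_pa_cohort(samples)
  peaks <- tibble::tibble(user_id = c("a", "b", "c"), attack_index = 1L,
                          t_seconds = 0)
  fit <- anxiety_slope(co, peaks)
  expect_equal(fit$slope, -1)
  expect_equal(fit$se, 0, tolerance = 1e-10)
  expect_equal(fit$n_points, 8L)
  td <- tidy(fit)
  expect_equal(td$estimate, -1)

  # constant ratings: slope exactly 0
  flat <- dplyr::bind_rows(hr, purrr::map(c("a", "b", "c"), function(id) {
    tibble::tibble(user_id = id, attack_index = 1L, channel = "anxiety",
                   t_seconds = c(0, 60, 120), value = 6)
  }) |> purrr::list_rbind())
  fit0 <- anxiety_slope(as_pa_cohort(flat), peaks)
  expect_equal(fit0$slope, 0)

  # all observations at a single timepoint: slope undefined
  one_t <- dplyr::bind_rows(hr, tibble::tibble(
    user_id = c("a", "b"), attack_index = 1L, channel = "anxiety",
    t_seconds = 60, value = c(5, 7)))
  expect_error(anxiety_slope(as_pa_cohort(one_t), peaks), "distinct times")
})

test_that("peak and duration summaries use sample conventions", {
  pk <- tibble::tibble(hr_at_peak = c(90, 100, 110))
  s <- summarize_peaks(pk)
  expect_equal(s$peak_hr_mean, 100)
  expect_equal(s$peak_hr_sd, 10)
  expect_false(s$degenerate)
  s1 <- summarize_peaks(pk[1, ])
  expect_equal(s1$peak_hr_sd, 0)
  expect_true(s1$degenerate)
  expect_error(summarize_peaks(pk[0, ]), "No peaks")

  # durations 2, 4, 6 minutes -> mean 4, sd 2
  samples <- purrr::map(1:3, function(i) {
    tibble::tibble(user_id = sprintf("u%d", i), attack_index = 1L,
                   channel = "hr", t_seconds = c(0, i * 120),
                   value = c(80, 85))
  }) |> purrr::list_rbind()
  d <- summarize_durations(as_pa_cohort(samples))
  expect_equal(d$duration_mean_min, 4)
  expect_equal(d$duration_sd_min, 2)

  # single-sample recording has duration zero
  single <- as_pa_cohort(tibble::tibble(
    user_id = "x", attack_index = 1L, channel = "hr",
    t_seconds = 30, value = 90))
  expect_equal(summarize_durations(single)$duration_mean_min, 0)
})

test_that("lifestyle and trigger summaries aggregate reported values only", {
  meta <- tibble::tibble(
    user_id = c("a", "b", "c"), attack_index = 1L,
    exercise = c(3L, 3L, 3L), sleep = c(3L, 3L, 3L), diet = c(3L, 3L, 3L),
    stress = c(2L, 4L, NA), substance_use = NA_integer_,
    trigger = c("health", "health", "conflict"))
  samples <- tibble::tibble(user_id = c("a", "b", "c"), attack_index = 1L,
                            channel = "hr", t_seconds = 0, value = 80)
  co <- as_pa_cohort(samples, meta)
  ls <- lifestyle_summary(co)
  expect_equal(ls$mean_rating[ls$factor == "stress"], 3)
  expect_equal(ls$n[ls$factor == "stress"], 2L)
  expect_false("substance_use" %in% ls$factor)
  expect_true(all(ls$mean_rating >= 1 & ls$mean_rating <= 5))

  tr <- trigger_frequencies(co)
  expect_equal(tr$count[tr$trigger == "health"], 2L)
  expect_equal(tr$proportion[tr$trigger == "health"], 2 / 3)
  expect_equal(sum(tr$proportion), 1)

  meta$trigger <- NA_character_
  expect_equal(nrow(trigger_frequencies(as_pa_cohort(samples, meta))), 0)
})

test_that("generator lifestyle and trigger structure is recovered at n = 500", {
  co <- generate_cohort(generator_config(n_recordings = 500, seed = 77))
  ls <- lifestyle_summary(co)
  expect_lt(ls$mean_rating[ls$factor == "stress"], 3)
  expect_gt(ls$mean_rating[ls$factor == "substance_use"], 3)
  tr <- trigger_frequencies(co)
  expect_equal(tr$trigger[1], "health")
})

test_that("percentages round half-up and complements close to 100", {
  expect_equal(percent(39, 123, 1), 31.7)
  expect_equal(percent(15, 16, 0), 94)
  expect_equal(percent(9, 16, 0), 56)
  expect_equal(percent(0, 7, 1), 0)
  expect_error(percent(1, 0), "denominator")
  expect_error(percent(5, 3), "numerator")
  set.seed(2)
  for (i in 1:50) {
    b <- sample(1:500, 1); a <- sample(0:b, 1)
    expect_lte(abs(percent(a, b, 1) + percent(b - a, b, 1) - 100), 0.1 + 1e-9)
  }
})
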