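test_that("first-peak detection follows the interior-maximum prominence rule", {
  expect_equal(
    detect_first_peak(series_tbl(c(0, 20, 40, 60), c(70, 92, 75, 72))),
    tibble::tibble(index = 2L, t_seconds = 20, hr_at_peak = 92)
  )
  # monotone rising: no interior maximum
  expect_null(detect_first_peak(series_tbl(c(0, 15, 30, 45),
                                           c(70, 80, 90, 95))))
  # rise of 3 bpm is below the 5 bpm prominence default
  expect_null(detect_first_peak(series_tbl(c(0, 20, 40), c(70, 73, 70))))
  # fewer than 3 samples cannot define an interior peak
  expect_null(detect_first_peak(series_tbl(c(0, 20), c(70, 95))))
  # the earliest qualifying peak wins, not the tallest
  two <- series_tbl(seq(0, 90, by = 15), c(70, 80, 70, 72, 95, 70, 68))
  expect_equal(detect_first_peak(two)$t_seconds, 15)
})

test_that("QC rejects short recordings before peak-free ones", {
  # 3 samples with a textbook peak shape: still rejected as short
  short_peaky <- tibble::tibble(
    user_id = "b", attack_index = 1L, channel = "hr",
    t_seconds = c(0, 15, 30), value = c(70, 95, 70))
  co <- tiny_cohort(
    extra_samples = short_peaky,
    extra_meta = tibble::tibble(user_id = "b", attack_index = 1L,
                                exercise = 3L, sleep = 3L, diet = 3L,
                                stress = 3L, substance_use = 3L,
                                trigger = NA_character_))
  rep <- qc_filter(co)$report
  expect_equal(rep$n_rejected_short, 1)
  expect_equal(rep$n_rejected_no_peak, 0)
  expect_equal(rep$n_included, 1)
})

test_that("filter report buckets partition any cohort exactly", {
  for (seed in c(3, 8)) {
    co <- generate_cohort(generator_config(n_recordings = 80, seed = seed))
    rep <- qc_filter(co)$report
    expect_equal(rep$n_rejected_short + rep$n_rejected_no_peak +
                   rep$n_included, rep$n_total)
    expect_equal(rep$n_total, 80)
    expect_equal(rep$frac_rejected_short,
                 percent(rep$n_rejected_short, rep$n_total, 1))
  }
  expect_error(qc_filter(subset_cohort(tiny_cohort(),
                                       tibble::tibble(user_id = character(),
                                                      attack_index = integer()))),
               "empty")
})

test_that("alignment masks exactly the observed peak-relative interval", {
  # the worked partial-coverage example: data at -17, -5, 0, 20, 33 s
  s <- series_tbl(c(-17, -5, 0, 20, 33) + 50, c(80, 90, 98, 88, 84))
  g <- align_and_grid(s, peak_t_seconds = 50)
  expect_equal(range(g$t[g$mask]), c(-15, 33))
  expect_true(all(is.na(g$value[!g$mask])))
  expect_true(all(!is.na(g$value[g$mask])))
  # mask support is one contiguous run
  runs <- rle(g$mask)
  expect_equal(sum(runs$values), 1)

  # linear midpoint
  g2 <- align_and_grid(series_tbl(c(0, 10), c(80, 90)), peak_t_seconds = 0)
  expect_equal(g2$value[g2$t == 5], 85)
  # exactness at sample points
  expect_equal(g2$value[g2$t == 0], 80)
  expect_equal(g2$value[g2$t == 10], 90)

  # a series entirely outside the window has an all-false mask
  g3 <- align_and_grid(series_tbl(c(100, 120), c(80, 85)), peak_t_seconds = 0)
  expect_false(any(g3$mask))
})

test_that("gridding reproduces affine series exactly over the support", {
  for (slope in c(-0.8, 0.3)) {
    tt <- sort(runif(12, -20, 70))
    s <- series_tbl(tt, 90 + slope * tt)
    g <- align_and_grid(s, peak_t_seconds = 0)
    expect_equal(g$value[g$mask], 90 + slope * g$t[g$mask], tolerance = 1e-10)
  }
})

test_that("zero-phase Butterworth matches its closed-form magnitude response", {
  dt <- 0.01
  t <- seq(0, 600, by = dt)
  mk <- function(f) {
    structure(tibble::tibble(t = t, value = sin(2 * pi * f * t),
                             mask = TRUE),
              class = c("pa_gridded", class(tibble::tibble())))
  }
  # two forward/backward passes square the 4th-order magnitude:
  # ratio(f) = 1 / (1 + (f / 0.1)^8)
  core <- function(g) {
    mid <- g$t > 100 & g$t < 500
    max(abs(g$value[mid]))
  }
  pass <- smooth_series(mk(0.01))
  expect_gte(core(pass), 0.99)
  stop <- smooth_series(mk(1))
  expect_lte(core(stop), 0.01)

  # DC gain is exactly 1: constants are invariant
  const <- gridded(function(t) rep(98, length(t)))
  sm <- smooth_series(const)
  expect_equal(sm$value[sm$mask], const$value[const$mask], tolerance = 1e-6)
  expect_identical(sm$mask, const$mask)
})

test_that("zero-phase filtering does not shift a symmetric bump's apex", {
  g <- gridded(function(t) 80 + 15 * exp(-((t - 10)^2) / (2 * 8^2)))
  sm <- smooth_series(g)
  expect_equal(g$t[which.max(g$value)], sm$t[which.max(sm$value)],
               tolerance = 0.02)
  expect_identical(sm$mask, g$mask)
})

test_that("supports too short to filter are passed through with a warning", {
  g <- gridded(function(t) 80 + t, support = c(0, 0.5))
  expect_warning(out <- smooth_series(g), "too short")
  expect_equal(out$value, g$value)
  expect_false(attr(out, "smoothed"))
})

test_that("demeaning zeroes the support mean and only the support", {
  const <- gridded(function(t) rep(98, length(t)), support = c(-10, 40))
  d <- demean_series(const)
  expect_true(all(d$value[d$mask] == 0))
  expect_true(all(is.na(d$value[!d$mask])))

  g <- gridded(function(t) 90 + t, support = c(-5, 25))
  d2 <- demean_series(g)
  expect_lt(abs(mean(d2$value[d2$mask])), 1e-9)

  empty <- gridded(function(t) t, support = c(100, 101))
  expect_error(demean_series(empty), "empty support")
})
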