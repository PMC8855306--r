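---
title: "Profiling real-world panic attacks from sparse smartphone biosignals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling real-world panic attacks from sparse smartphone biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panicprofiler)
```

## The problem

Panic attacks (PAs) are abrupt surges of fear with strong autonomic
arousal. Smartphone apps can capture them in the wild: the phone camera
provides photoplethysmographic heart rate (HR, in bpm) every time the user
completes a prompt cycle, and the user rates their subjective anxiety on a
0--10 scale. The resulting recordings are short, sparse (one HR sample
every ~15--30 s, anxiety rarer still), irregularly timed, start at an
arbitrary point of the attack, and often fail basic quality checks.
`panicprofiler` implements the analysis chain that turns a cohort of such
recordings into an average physiological profile of the attack, plus a
synthetic-cohort generator that emulates the data-generating process so
the whole chain can be validated end to end.

The pipeline has four stages:

1. **Inclusion filter** (`qc_filter()`): a recording must have at least 4
   HR samples and a clear first HR peak. In the motivating field data,
   54.1% of 148 first recordings failed the sample-count rule and a
   further 12.2% had no clear peak, leaving 50.
2. **Peak-relative standardisation** (`detect_first_peak()`,
   `align_and_grid()`): because users start recording at unpredictable
   moments, each series is re-timed relative to its first HR peak — an
   easily identifiable feature of the attack — and linearly interpolated
   onto a uniform 0.01 s grid over the window −15 s to +60 s around the
   peak. No extrapolation is performed: a coverage mask records the
   contiguous sub-interval actually observed, e.g. samples at −17, −5, 0,
   20 and 33 s cover exactly [−15, 33] s.
3. **Zero-phase smoothing** (`smooth_series()`): a 4th-order Butterworth
   low-pass at 0.1 Hz, applied forward and backward so features are not
   shifted in time.
4. **Partial-coverage ensemble averaging** (`ensemble_average()`): the
   per-gridpoint mean over exactly those series whose mask covers that
   instant, with the contributing count reported per gridpoint. Anxiety
   series are aligned by the *same recording's HR peak* and processed
   identically — there is no separate anxiety peak detection, since the
   HR peak is the physiological anchor of the attack.

From the profile and the included recordings the package derives the
cohort statistics: peak HR mean/SD, recording duration, time for the
ensemble to recover to 85 bpm, the ensemble peak-to-plateau excursion,
prominent-cycle counts, the pooled anxiety recovery slope, lifestyle
contributor means, trigger frequencies, and survey-style percentages
(`percent()`, half-up rounding, so 80/148 prints as 54.1%).

## What "clear peak" means

The field data did not define "clear peak" operationally, so the package
does: the first interior sample strictly greater than both neighbours that
exceeds the minimum of all *preceding* samples by at least 5 bpm
(configurable). The preceding-minimum form is the natural definition for a
*first* peak — the rise from the pre-peak baseline is what identifies the
onset of arousal — and 5 bpm is large relative to the 1--2 bpm jitter of
camera-based HR estimates but small relative to the ~15 bpm excursions of
an attack. The sample-count rule is checked before the peak rule, so the
two rejection buckets partition the cohort.

Cycle *counting* (`count_cycles()`) needs a different prominence notion:
applied to every maximum of a long noisy series, the preceding-minimum
rule degenerates (once HR has risen 5 bpm above the running minimum, every
later noise blip qualifies). Counting therefore uses topographic
prominence — height above the higher of the two bracketing minima, the
standard peak-finding definition — with at most one counted apex per 30 s,
and, when the sampling is dense enough to resolve it (median gap below
2.5 s), the same 0.1 Hz low-pass as the profiling stage is applied first.
Arousal cycles are minutes apart; fluctuations faster than 0.1 Hz are
measurement noise by the pipeline's own frequency criterion.

## Numerical choices

* **Grid**: 0.01 s steps, both window endpoints included (7501 points on
  [−15, 60]). Interpolation is exact for affine series and never invents
  data outside the observed span.
* **Filtering**: the "4th order, zero phase" filter is read as a 4th-order
  prototype applied forward and backward, i.e. an 8th-order magnitude
  response $|H(f)|^2 = (1 + (f/f_c)^8)^{-1}$ with $f_c = 0.1$ Hz and no
  phase distortion. Supports are padded by odd reflection up to three
  characteristic lengths ($3/f_c$) and each pass starts from the steady
  state of the segment's first value, so constants pass through exactly
  and edge transients are negligible even on short supports. Supports
  shorter than 1 s are returned unchanged with a warning.
* **Recovery time**: first crossing of the threshold (default 85 bpm) at
  or after the aligned peak, linearly interpolated between grid points;
  `NA` if the profile never reaches it inside the covered window.
* **Anxiety slope**: ordinary least squares of the raw sparse ratings on
  minutes since the HR peak, pooled over recordings and restricted to
  t ≥ 0. Regressing the interpolated 100 Hz anxiety grid instead would
  pseudo-replicate each rating thousands of times and produce an
  absurdly small standard error; the raw-rating regression is the
  statistically defensible variant. Because ratings within a recording
  share that recording's level, the reported standard error is
  cluster-robust (clustered by recording) — the model-based OLS standard
  error would understate the pooled slope's uncertainty several-fold.
* **Percentages**: half-up rounding at the stated number of decimals,
  matching the reporting convention of the survey summaries (9/16 → 56 at
  zero decimals).
* **SDs** use the sample (n − 1) convention; a single-recording summary
  reports SD 0 with a degenerate-sample flag.

## The synthetic cohort generator

`generate_cohort()` emulates the app's data-generating process under the
published study conditions, which are its defaults:

| Parameter | Default | Meaning |
|---|---|---|
| `peak_hr_mean`, `peak_hr_sd` | 98, 21.56 bpm | per-attack peak HR law |
| `baseline_hr_mean` | 83 bpm | inter-cycle baseline; mean arousal excursion 98 − 83 = 15 bpm |
| `duration_mean_min`, `duration_sd_min` | 4.64, 6.27 min | recording-duration law |
| `n_cycles_mean`, `cycle_period_s` | 4, 150 s | ~4 arousal cycles per 10-minute attack |
| `recovery_tau_s` | 30 s | target ensemble recovery time to 85 bpm |
| `anxiety_slope_per_min` | −0.43 | latent linear anxiety decline |
| `hr_sample_interval_s` | 15 s | mean HR sampling cadence (Gamma-jittered) |
| `p_too_short`, `p_no_peak` | 0.541, 0.122 | observed failure-mode rates |

Each attack's latent HR trajectory is a baseline plus a train of
raised-cosine bumps — smooth, compactly supported, so inter-cycle segments
sit exactly at baseline — with per-cycle amplitudes decaying by 0.85 so
the first peak is the global maximum (it is the alignment anchor).
Design choices worth spelling out:

* **Peak/baseline coupling.** The peak HR is drawn from the configured
  Normal law exactly; the arousal amplitude is drawn *conditionally*
  (Normal around 15 bpm, SD `baseline_hr_sd` = 5, truncated at 6 bpm so
  every well-formed attack is detectable) and the baseline is peak minus
  amplitude. Drawing baseline and peak independently with a 21.56 bpm
  peak SD would give a third of attacks sub-detectable excursions, and
  the selection induced by the peak filter would then badly distort the
  detected-peak distribution.
* **Durations** are log-normal, moment-matched to mean 4.64 / SD 6.27 min
  and truncated to [0.5, 30] min; an SD larger than the mean rules out a
  symmetric law.
* **Bump width.** The half-width is 1.1 × `recovery_tau_s`. The factor
  is calibrated so that the *ensemble* — widened relative to the latent
  bump by apex-sampling jitter (±half a sampling interval) and by the
  0.1 Hz smoothing — first crosses 85 bpm about `recovery_tau_s` seconds
  after the peak under the default configuration.
* **Cycle counts** per attack are a rounded Normal(4, 1) floored at 1:
  "approximately four cycles per attack" implies low dispersion.
* **Anxiety** declines linearly from an integer start drawn uniformly in
  5--9, with Gaussian noise (SD 0.5), rounded to integers and clipped to
  0--10. Prompting stops after a cohort-constant window: the time at
  which the *lowest* configured starting rating would decline to 1
  (≈ 9.3 min under defaults). Users whose attack has resolved stop
  rating; statistically, the cap keeps ratings off the scale floor (a
  floor-censored decline would attenuate the pooled slope) and, because
  it does not depend on the recording's own starting rating, the
  observation window carries no information about the intercept, so the
  pooled OLS slope stays unbiased.
* **Failure modes.** "Too short" recordings keep only their first 1--3 HR
  samples (app terminated early). "No peak" recordings start *after* the
  attack's apex and sample only the decaying limb — the post-peak variant
  observed in the field data — with at least 4 samples so the
  sample-count rule does not fire first. `make_fixture_cohort()` builds
  the deterministic analogue with *exact* counts (its peak-free series
  are exactly monotone), which is what the filter-count checks use.
* **Reproducibility.** One RNG stream per cohort: the cohort seed derives
  a sub-seed per recording, identical configurations give byte-identical
  cohorts, and the caller's RNG state is untouched.

## What the generator does and does not emulate

It reproduces the sparse irregular sampling, the peak-anchored cyclical
arousal with realistic between-attack heterogeneity, the linearly
declining integer anxiety ratings, the two QC failure modes at their
observed rates, and lifestyle/trigger metadata with the reported ordering
(health the modal trigger; stress, diet, sleep and exercise slightly worse
than typical; substance use slightly better). It does *not* emulate raw
photoplethysmogram waveforms (HR values are generated directly),
between-attack dynamics within a user (habituation, biofeedback learning),
non-stationary baselines, or motion artifacts beyond white measurement
noise. Passing parameter-recovery tests therefore validates the analysis
chain's correctness and calibration, not the generator's fidelity to every
property of real field data.

## Sampling variability of the headline statistics

With the defaults, a 1000-recording cohort retains roughly 280 recordings
after QC. At that size the detected-peak mean carries a standard error of
~1.3 bpm — plus an intrinsic ~1 bpm shortfall relative to the latent peak
law, because the detected peak is a sparse sample *near*, not at, the
apex of a ~66 s-wide bump. The recovery time is the noisiest statistic:
the 85 bpm threshold sits only ~2 bpm above the ~83 bpm plateau, whose
sampling error is ~1.5 bpm, so the crossing time inherits a spread of
several seconds. This is why the package's own end-to-end checks run the
default conditions at the upper end of their tested cohort-size range
(n = 1000) and compare ensemble-shape quantities within ±20%, the
precision with which they are stated ("about 15 bpm", "approximately 30
seconds").

## A worked run

```{r example, eval = FALSE}
library(panicprofiler)

cohort <- generate_cohort(generator_config(n_recordings = 500, seed = 7))
qc <- qc_filter(cohort)
qc$report

profile <- profile_cohort(qc)
recovery_time(profile)          # seconds to fall to 85 bpm
autoplot(profile)
plot_demeaned_traces(profile)

fit <- anxiety_slope(qc$included, qc$peaks)
tidy(fit)

summary <- cohort_summary(cohort)
glance(summary)
```

The vignette deliberately keeps the chunks unevaluated; the same
quantities are computed by the test suite and by `scripts/acceptance.R`,
which is the reproducible record of the numbers.

## Known limitations

* The inclusion filter implements exactly the two published rules; it
  does not attempt artifact detection (e.g. implausible HR jumps).
* The anxiety profile is anchored to the HR peak; if HR and anxiety were
  desynchronised in a way the field data did not show, the anchor would
  blur the anxiety ensemble.
* `recovery_time()` reports the first crossing; a profile that dips and
  rebounds near the threshold reports the dip.
* Whether the field analysis detected the first peak on raw or
  pre-smoothed samples is not stated; the package detects on raw samples
  (alignment precedes smoothing in the processing order), which is robust
  because the prominence rule already rejects sub-5 bpm jitter.
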