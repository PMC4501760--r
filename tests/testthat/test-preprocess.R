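test_that("boost gain matches its piecewise closed form on a dense grid", {
  cfg <- preprocess_config()
  f <- 10^seq(-3, 3, length.out = 400)
  expected_db <- pmin(pmax(20 * log10(100 / f), 0), 60)
  expect_equal(20 * log10(boost_gain(f, cfg)), expected_db, tolerance = 1e-9)
  # 0.01 Hz hits the 60 dB cap, not 80 dB
  expect_equal(boost_gain(0.01, cfg), 1000)
  expect_equal(boost_gain(0.1, cfg), 1000)
})

test_that("low-frequency boost amplifies 10 Hz by 20 dB and spares 1 kHz", {
  sr <- 8000
  n <- 8000  # 1 s so that 10 Hz and 1 kHz sit exactly on FFT bins
  t <- (0:(n - 1)) / sr
  ts <- make_trial_set(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 1000 * t)),
                       sample_rate = sr)
  out <- low_freq_boost(ts, preprocess_config())
  amp10 <- max(abs(out$trials[1, ]))
  amp1000 <- max(abs(out$trials[2, ]))
  expect_equal(amp10, 10, tolerance = 0.01)
  expect_equal(amp1000, 1, tolerance = 0.001)
})

test_that("boost equals a full FFT gain multiply", {
  withr::with_seed(14, x <- matrix(rnorm(3 * 500), 3, 500))
  ts <- make_trial_set(x, sample_rate = 2000)
  out <- low_freq_boost(ts, preprocess_config())$trials
  cfg <- preprocess_config()
  for (r in 1:3) {
    f <- (0:499) * 2000 / 500
    g <- boost_gain(pmin(f, 2000 - f), cfg)
    oracle <- Re(fft(fft(x[r, ]) * g, inverse = TRUE)) / 500
    expect_equal(out[r, ], oracle, tolerance = 1e-9)
  }
})

test_that("bandpass removes DC, preserves mid-band tones at zero lag", {
  sr <- 8000
  n <- 2000
  t <- (0:(n - 1)) / sr
  tone <- sin(2 * pi * 500 * t)
  ts <- make_trial_set(rbind(rep(5, n), tone), sample_rate = sr)
  out <- bandpass(ts, preprocess_config())
  expect_lt(abs(mean(out$trials[1, ])), 1e-6)
  mid <- 500:1500  # avoid edge transients
  expect_equal(max(abs(out$trials[2, mid])), 1, tolerance = 0.05)
  cc <- ccf(out$trials[2, mid], tone[mid], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("stop-band attenuation matches the analytic Butterworth magnitude", {
  sr <- 8000
  n <- 16000  # 2 s: enough cycles of 17.5 Hz for a steady measurement
  t <- (0:(n - 1)) / sr
  tone <- sin(2 * pi * 17.5 * t)
  cfg <- preprocess_config()
  out <- bandpass(make_trial_set(matrix(tone, 1), sample_rate = sr), cfg)
  mid <- 4000:12000
  meas_db <- 20 * log10(rms(out$trials[1, mid]) / rms(tone[mid]))
  bf <- signal::butter(cfg$filter_order, cfg$band / (sr / 2), type = "pass")
  # analytic |H| of the designed digital filter at 17.5 Hz
  w <- 2 * pi * 17.5 / sr
  ejw <- exp(-1i * w * (seq_along(bf$b) - 1))
  H <- sum(bf$b * ejw) / sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
  expect_equal(meas_db, 2 * 20 * log10(Mod(H)), tolerance = 1)  # two passes
  # and the two-pass roll-off is at least the one-pass design slope
  expect_lt(meas_db, -24)
})

test_that("zero-phase filtering shifts a transient by less than 0.1 ms", {
  sr <- 8000
  n <- 2000
  t_ms <- -40 + 1000 * (0:(n - 1)) / sr
  transient <- exp(-(t_ms - 35)^2 / (2 * 0.35^2))
  cfg <- preprocess_config()
  out <- bandpass(make_trial_set(matrix(transient, 1), sample_rate = sr), cfg)
  # oracle: ideal zero-phase FFT mask with the same band edges
  f <- (0:(n - 1)) * sr / n
  absf <- pmin(f, sr - f)
  mask <- as.numeric(absf >= cfg$band[1] & absf <= cfg$band[2])
  oracle <- Re(fft(fft(transient) * mask, inverse = TRUE)) / n
  win <- which(t_ms >= 20 & t_ms <= 60)
  lat_filt <- t_ms[win[which.max(out$trials[1, win])]]
  lat_oracle <- t_ms[win[which.max(oracle[win])]]
  expect_lt(abs(lat_filt - lat_oracle), 0.1)
})

test_that("band edges at or above Nyquist are rejected", {
  ts <- make_trial_set(matrix(rnorm(100), 1), sample_rate = 3000)
  expect_error(bandpass(ts, preprocess_config(band = c(70, 2000))), "Nyquist|inside")
})

test_that("epoching crops and baselining zeroes the pre-stimulus mean", {
  cfg <- preprocess_config()
  ts <- make_trial_set(rep_rows(rep(3, 2000), 2))
  out <- epoch_baseline(ts, cfg)
  expect_true(all(out$trials == 0))

  withr::with_seed(3, x <- matrix(rnorm(4 * 2000), 4, 2000))
  out2 <- epoch_baseline(make_trial_set(x), cfg)
  base <- .window_idx(ncol(out2$trials), 8000, out2$t0, -40, 0)
  expect_true(all(abs(rowMeans(out2$trials[, base])) < 1e-9))

  # already zero-mean pre-stimulus: unchanged
  y <- x - rowMeans(x[, base])
  out3 <- epoch_baseline(make_trial_set(y), cfg)
  expect_equal(out3$trials, y, tolerance = 1e-12)
})

test_that("school-age epoch yields a 230 ms window from the same trials", {
  ts <- make_trial_set(rep_rows(rnorm(2000), 2))
  pre <- epoch_baseline(ts, preprocess_config(epoch = c(-40, 210)))
  sch <- epoch_baseline(ts, preprocess_config(epoch = c(-40, 190)))
  expect_equal(ncol(pre$trials), 2000)   # 250 ms at 8 kHz
  expect_equal(ncol(sch$trials), 1841)   # 230 ms at 8 kHz, inclusive ends
})

test_that("artifact rejection is strict and removes exactly the planted trials", {
  withr::with_seed(8, x <- matrix(rnorm(20 * 500), 20, 500))
  planted <- c(3L, 11L, 17L)
  x[planted, 250] <- 40 * c(1, -1, 1)
  x[5, 100] <- 35.0  # exactly at threshold: retained
  ts <- make_trial_set(x)
  out <- reject_artifacts(ts, preprocess_config())
  expect_identical(out$rejected_idx, planted)
  expect_equal(nrow(out$trials), 17)
  expect_error(
    reject_artifacts(make_trial_set(matrix(100, 2, 10)), preprocess_config()),
    "35")
})

test_that("polarity addition cancels inverting components and keeps invariant ones", {
  sr <- 8000
  n <- 2000
  t <- (0:(n - 1)) / sr
  inverting <- sin(2 * pi * 100 * t)
  x <- rbind(inverting, -inverting, inverting, -inverting)
  ts <- make_trial_set(x, sample_rate = sr)
  avg <- combine_polarities_and_average(ts, preprocess_config(final_sweeps = 4))
  expect_lt(max(abs(avg$samples)), 0.01 * max(abs(inverting)))

  invariant <- 0.5 * sin(2 * pi * 100 * t)
  ts2 <- make_trial_set(rep_rows(invariant, 4), sample_rate = sr)
  avg2 <- combine_polarities_and_average(ts2, preprocess_config(final_sweeps = 4))
  expect_equal(avg2$samples, invariant, tolerance = 1e-12)
  expect_equal(avg2$n_sweeps_included, 4)
})

test_that("final average draws exactly final_sweeps, balanced by polarity", {
  spec <- cohort_spec(n_trials_per_child = 4200, artifact_rate = 0)
  ts <- generate_trials(response_template(), spec, seed = 6)
  pp <- preprocess_trials(ts, preprocess_config())
  expect_equal(pp$log$n_rejected, 0)
  expect_equal(pp$average$n_sweeps_included, 4000)
  expect_error(
    combine_polarities_and_average(
      make_trial_set(matrix(0, 10, 100)), preprocess_config(final_sweeps = 12)),
    "insufficient balanced")
})

test_that("the chain is bit-reproducible for identical input and config", {
  spec <- cohort_spec(n_trials_per_child = 60, artifact_rate = 0.05)
  ts <- generate_trials(response_template(), spec, seed = 10)
  p1 <- preprocess_trials(ts, preprocess_config(final_sweeps = 40))
  p2 <- preprocess_trials(ts, preprocess_config(final_sweeps = 40))
  expect_identical(p1$average$samples, p2$average$samples)
  expect_identical(p1$log, p2$log)
})
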