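gauss_response <- function(centers_ms, amps = rep(1, length(centers_ms)),
                           sr = 8000, sigma = 0.35) {
  t <- -40 + 1000 * (0:(0.25 * sr - 1)) / sr
  x <- numeric(length(t))
  for (j in seq_along(centers_ms))
    x <- x + amps[j] * exp(-(t - centers_ms[j])^2 / (2 * sigma^2))
  average_response(x, sr, t0 = -40, n_sweeps_included = 1)
}

test_that("a single transient is located to within one sample period", {
  avg <- gauss_response(31.0)
  pk <- detect_peaks(avg)
  expect_lte(abs(pk[["peak_latency_31"]] - 31.0), 1000 / avg$sample_rate)
  expect_true(is.na(pk[["peak_latency_21"]]))
  expect_true("peak_latency_21" %in% attr(pk, "missing"))
})

test_that("a monotone ramp yields a flagged missing peak", {
  sr <- 8000
  t <- -40 + 1000 * (0:1999) / sr
  avg <- average_response(t, sr, t0 = -40, n_sweeps_included = 1)
  pk <- detect_peaks(avg)
  expect_true(all(is.na(pk)))
  expect_length(attr(pk, "missing"), 4)
})

test_that("peak picking is invariant to a constant offset", {
  avg <- gauss_response(c(21.4, 31.2, 41.0, 50.8), amps = c(1, .9, .8, .7))
  pk1 <- detect_peaks(avg)
  avg$samples <- avg$samples + 5
  pk2 <- detect_peaks(avg)
  expect_identical(pk1[1:4], pk2[1:4])
})

test_that("planted peaks survive the full pipeline at high SNR", {
  tpl <- response_template(peak_latencies = c(p21 = 21.4, p31 = 31.2,
                                              p41 = 41.0, p51 = 50.8))
  spec <- cohort_spec(n_trials_per_child = 4200, artifact_rate = 0)
  ts <- generate_trials(tpl, spec, seed = 17, jitter_sd = 0.1, noise_sd = 0.1)
  pp <- preprocess_trials(ts)
  pk <- detect_peaks(pp$average)
  expect_true(all(abs(pk[1:4] - tpl$peak_latencies) <= 0.5))
})

test_that("identical trials give perfect, clipped stability", {
  x <- rep_rows(sin(2 * pi * 100 * (0:1999) / 8000), 8)
  ts <- make_trial_set(x)
  st <- response_stability(ts, stability_config(n_pairs = 10, seed = 1))
  expect_equal(st$stability_r, 1.0)
  expect_true(st$clipped)
  expect_equal(st$stability_z, atanh(1 - 1e-12))
})

test_that("pure-noise stability is near zero with 4,000 sweeps", {
  withr::with_seed(23, x <- matrix(rnorm(4000 * 640), 4000, 640))
  ts <- make_trial_set(x, t0 = 0, epoch_window = c(0, 80))
  st <- response_stability(ts, stability_config(n_pairs = 100, seed = 5))
  expect_lt(abs(st$stability_r), 0.05)
})

test_that("the Fisher transform is the analytic atanh", {
  expect_equal(atanh(0.75), 0.9730, tolerance = 1e-4)
  x <- rep_rows(sin(2 * pi * 300 * (0:639) / 8000), 6) +
    matrix(rnorm(6 * 640, sd = 0.5), 6)
  ts <- make_trial_set(x, t0 = 0, epoch_window = c(0, 80))
  st <- response_stability(ts, stability_config(n_pairs = 50, seed = 2))
  expect_equal(st$stability_z, atanh(st$stability_r), tolerance = 1e-12)
})

test_that("per-pair correlations match a from-scratch replay of the partition", {
  withr::with_seed(31, x <- matrix(rnorm(12 * 640), 12, 640) +
                     rep(sin(2 * pi * 150 * (0:639) / 8000), each = 12))
  ts <- make_trial_set(x, t0 = 0, epoch_window = c(0, 80))
  cfg <- stability_config(n_pairs = 100, window = c(20, 60), seed = 77)
  st <- response_stability(ts, cfg)
  # replay: same RNG stream, same partition scheme, plain cor()
  ic <- which(ts$polarity == "condensation")
  ir <- which(ts$polarity == "rarefaction")
  idx <- .window_idx(640, 8000, 0, 20, 60)
  r_replay <- withr::with_seed(77, vapply(1:100, function(p) {
    hc <- sample.int(length(ic), length(ic) / 2)
    hr <- sample.int(length(ir), length(ir) / 2)
    a <- (colMeans(x[ic[hc], idx]) + colMeans(x[ir[hr], idx])) / 2
    b <- (colMeans(x[ic[-hc], idx]) + colMeans(x[ir[-hr], idx])) / 2
    cor(a, b)
  }, numeric(1)))
  expect_equal(st$r_pairs, r_replay, tolerance = 1e-12)
})

test_that("odd trial counts per polarity are handled by dropping one trial", {
  x <- matrix(rnorm(7 * 640), 7, 640)
  ts <- make_trial_set(x, t0 = 0, epoch_window = c(0, 80))
  st <- response_stability(ts, stability_config(n_pairs = 5, seed = 1))
  expect_equal(st$n_trials_used, 6)
})

test_that("spectral amplitudes are zero for silence and linear in scale", {
  sr <- 8000
  zero <- average_response(numeric(2000), sr, -40, 1)
  expect_true(all(spectral_amplitudes(zero)[1:4] == 0))

  withr::with_seed(5, x <- rnorm(2000))
  a1 <- spectral_amplitudes(average_response(x, sr, -40, 1))
  a3 <- spectral_amplitudes(average_response(3 * x, sr, -40, 1))
  expect_equal(a3, 3 * a1, tolerance = 1e-12)
})

test_that("a pure 500 Hz tone matches the analytic windowed-DFT oracle", {
  sr <- 8000
  A <- 0.8
  t <- -40 + 1000 * (0:1999) / sr
  x <- A * sin(2 * pi * 500 * (t - 20) / 1000)
  avg <- average_response(x, sr, -40, 1)
  cfg <- spectral_config()
  h <- spectral_amplitudes(avg, cfg)

  # oracle: direct windowed DFT of the segment, evaluated by explicit sums
  seg_idx <- which(t >= 20 & t <= 60)
  seg <- x[seg_idx]
  n <- length(seg)
  tt <- (0:(n - 1)) * 1000 / sr
  w <- rep(1, n)
  up <- tt < 10; dn <- tt > tt[n] - 10
  w[up] <- 0.5 * (1 - cos(pi * tt[up] / 10))
  w[dn] <- 0.5 * (1 - cos(pi * (tt[n] - tt[dn]) / 10))
  nfft <- 4096
  freqs <- (0:(nfft - 1)) * sr / nfft
  bin <- which(freqs >= 480 - 1e-9 & freqs <= 520 + 1e-9)
  dft_amp <- vapply(bin, function(k) {
    ph <- -2 * pi * (k - 1) * (0:(n - 1)) / nfft
    2 * Mod(sum(seg * w * complex(real = cos(ph), imaginary = sin(ph)))) / n
  }, numeric(1))
  expect_equal(unname(h["h5"]), mean(dft_amp), tolerance = 1e-10)
  # and the bin mean is within 2% of the same oracle recomputed coarsely
  expect_equal(unname(h["h5"]) / mean(dft_amp), 1, tolerance = 0.02)
  # leakage into neighbouring bins is bounded
  expect_gt(h[["h5"]], 5 * h[["h4"]])
  expect_gt(h[["h5"]], 5 * h[["h6"]])
})

test_that("stability decreases in noise and increases with per-trial SNR", {
  grid <- c(0.2, 0.4, 0.8, 1.6, 3.2)
  sig <- sin(2 * pi * c(100, 500) %o% ((0:639) / 8000))
  sig <- 0.3 * colSums(sig)
  for (seed in 1:3) {
    z <- vapply(grid, function(ns) {
      withr::with_seed(1000 * seed, {
        x <- rep_rows(sig, 200) + matrix(rnorm(200 * 640, sd = ns), 200)
      })
      ts <- make_trial_set(x, t0 = 0, epoch_window = c(0, 80))
      response_stability(ts, stability_config(n_pairs = 60, seed = seed))$stability_z
    }, numeric(1))
    expect_true(all(diff(z) < 0))
  }
})

test_that("compute_metrics bundles deterministically and recovers a clean template", {
  tpl <- response_template()
  spec <- cohort_spec(n_trials_per_child = 400, artifact_rate = 0)
  ts <- generate_trials(tpl, spec, seed = 2, jitter_sd = 0, noise_sd = 0.05)
  pp <- preprocess_trials(ts, preprocess_config(final_sweeps = 400))
  m1 <- compute_metrics(pp$average, pp$retained,
                        stab_cfg = stability_config(seed = 9))
  m2 <- compute_metrics(pp$average, pp$retained,
                        stab_cfg = stability_config(seed = 9))
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_true(all(abs(unlist(m1[1, paste0("peak_latency_", c(21, 31, 41, 51))]) -
                        tpl$peak_latencies) <= 0.5))
  expect_gt(m1$stability_z, 2)
})
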