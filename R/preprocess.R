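#' Preprocessing configuration
#'
#' Parameters of the offline FFR preprocessing chain, applied in a fixed
#' order: frequency-domain low-frequency boost, zero-phase Butterworth
#' band-pass, epoching and baselining, amplitude artifact rejection, and
#' polarity-added averaging.
#'
#' @param boost_corner Corner of the low-frequency boost in Hz; gain is 0 dB
#'   at and above it.
#' @param boost_slope Boost slope in dB per decade below the corner.
#' @param boost_decades Number of decades over which the boost rises before
#'   it is capped (cap = `boost_slope * boost_decades` dB).
#' @param band Band-pass edges in Hz, `c(low, high)`.
#' @param filter_order Butterworth band-pass order per pass (2 gives the
#'   12 dB/octave design roll-off; the forward-backward pass doubles it).
#' @param epoch Epoch limits in ms (`c(-40, 210)` for the preschool
#'   protocol, `c(-40, 190)` for school age).
#' @param baseline_window Window (ms) whose per-trial mean is subtracted.
#' @param artifact_threshold Rejection threshold in uV; a trial is removed
#'   iff any sample strictly exceeds it in absolute value.
#' @param final_sweeps Number of sweeps entering the final average (even;
#'   half per polarity).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(boost_corner = 100,
                              boost_slope = 20,
                              boost_decades = 3,
                              band = c(70, 2000),
                              filter_order = 2,
                              epoch = c(-40, 210),
                              baseline_window = c(-40, 0),
                              artifact_threshold = 35,
                              final_sweeps = 4000) {
  if (epoch[1] >= 0 || epoch[2] <= 0)
    stop("epoch must straddle stimulus onset (start < 0 < end)")
  if (final_sweeps %% 2 != 0) stop("final_sweeps must be even")
  if (artifact_threshold <= 0) stop("artifact_threshold must be positive")
  structure(list(
    boost_corner = boost_corner, boost_slope = boost_slope,
    boost_decades = boost_decades, band = band, filter_order = filter_order,
    epoch = epoch, baseline_window = baseline_window,
    artifact_threshold = artifact_threshold, final_sweeps = final_sweeps
  ), class = "preprocess_config")
}

#' Low-frequency boost gain function
#'
#' Gain (linear) applied in the frequency domain: 0 dB at and above the
#' corner, rising `boost_slope` dB per decade below it, capped at
#' `boost_slope * boost_decades` dB.
#'
#' @param freq_hz Frequencies (Hz, non-negative) to evaluate.
#' @param cfg A [preprocess_config()].
#' @return Linear gain values.
#' @export
boost_gain <- function(freq_hz, cfg = preprocess_config()) {
  cap_db <- cfg$boost_slope * cfg$boost_decades
  f <- pmax(freq_hz, .Machine$double.xmin)
  db <- pmin(pmax(cfg$boost_slope * log10(cfg$boost_corner / f), 0), cap_db)
  10^(db / 20)
}

# Multiply each row's DFT by a real, even gain g(|f|), exactly, touching
# only the bins where the gain differs from 1: the output is the input plus
# the inverse DFT of (gain - 1) times those bins' DFT coefficients, done in
# real arithmetic. Equivalent to fft -> multiply -> ifft, but O(n_bins
# changed) instead of O(N log N) per trial.
#' @noRd
.apply_freq_gain <- function(x, sample_rate, gain_fun) {
  N <- ncol(x)
  binf <- (seq_len(N) - 1) * sample_rate / N
  absf <- pmin(binf, sample_rate - binf)         # |f| of each FFT bin
  g_all <- gain_fun(absf)
  kset <- which(abs(g_all - 1) > 1e-15)          # includes conjugate bins
  if (!length(kset)) return(x)
  g <- g_all[kset]
  ang <- -2 * pi * outer(seq_len(N) - 1, kset - 1) / N   # N x |kset|
  Wr <- cos(ang); Wi <- sin(ang)
  Cr <- sweep(x %*% Wr, 2, g - 1, "*")
  Ci <- sweep(x %*% Wi, 2, g - 1, "*")
  # Re(C %*% t(Conj(W))) / N, in real arithmetic
  x + (Cr %*% t(Wr) + Ci %*% t(Wi)) / N
}

#' Frequency-domain low-frequency amplification
#'
#' Multiplies each trial's spectrum by the real, even [boost_gain()]
#' (epoch-length FFT, no windowing), reconstructing low-frequency energy
#' attenuated by the online acquisition high-pass.
#'
#' @param trials A `trial_set`.
#' @param cfg A [preprocess_config()].
#' @return The boosted `trial_set`.
#' @export
low_freq_boost <- function(trials, cfg = preprocess_config()) {
  trials$trials <- .apply_freq_gain(trials$trials, trials$sample_rate,
                                    function(f) boost_gain(f, cfg))
  trials
}

# Steady-state initial state of the direct-form II transposed filter for a
# unit step input (the lfilter_zi construction): scaling it by the first
# sample makes the response to a constant input its exact steady state.
#' @noRd
.filter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b)) - 1
  a <- c(a, numeric(n + 1 - length(a)))
  b <- c(b, numeric(n + 1 - length(b)))
  # companion matrix of a (transposed), as in the standard construction
  comp <- rbind(-a[-1], cbind(diag(n - 1), 0))
  IminusA <- diag(n) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(IminusA, B))
}

# Zero-phase filtering of each matrix row: odd-reflection padding, forward
# pass, reversed backward pass, steady-state initial conditions (same
# scheme as standard filtfilt).
#' @noRd
.filtfilt_rows <- function(b, a, x) {
  .filtfilt_rows_cpp(as.numeric(b), as.numeric(a),
                     .filter_zi(as.numeric(b), as.numeric(a)), x)
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the configured Butterworth band-pass (order `filter_order` per
#' pass, i.e. 12 dB/octave skirts at the default order 2) forward and
#' backward over each trial, so the net phase shift is zero and the
#' effective roll-off is doubled.
#'
#' @param trials A `trial_set`.
#' @param cfg A [preprocess_config()].
#' @return The filtered `trial_set`.
#' @export
bandpass <- function(trials, cfg = preprocess_config()) {
  nyq <- trials$sample_rate / 2
  if (any(cfg$band >= nyq) || any(cfg$band <= 0))
    stop(sprintf("band edges must lie strictly inside (0, %g) Hz", nyq))
  bf <- signal::butter(cfg$filter_order, cfg$band / nyq, type = "pass")
  trials$trials <- .filtfilt_rows(bf$b, bf$a, trials$trials)
  trials
}

#' Epoch and baseline trials
#'
#' Crops each trial to the configured epoch and subtracts the per-trial mean
#' of the baseline window (default -40 to 0 ms).
#'
#' @param trials A `trial_set`.
#' @param cfg A [preprocess_config()].
#' @return The epoched, baselined `trial_set`.
#' @export
epoch_baseline <- function(trials, cfg = preprocess_config()) {
  n <- ncol(trials$trials)
  keep <- .window_idx(n, trials$sample_rate, trials$t0,
                      cfg$epoch[1], cfg$epoch[2])
  if (!length(keep)) stop("epoch window lies outside the trial extent")
  x <- trials$trials[, keep, drop = FALSE]
  t0 <- trials$t0 + 1000 * (keep[1] - 1) / trials$sample_rate
  base <- .window_idx(ncol(x), trials$sample_rate, t0,
                      cfg$baseline_window[1], cfg$baseline_window[2])
  if (!length(base)) stop("baseline window is empty")
  x <- x - rowMeans(x[, base, drop = FALSE])
  trials$trials <- x
  trials$t0 <- t0
  trials$epoch_window <- cfg$epoch
  trials
}

#' Amplitude artifact rejection
#'
#' Removes every trial containing any sample whose absolute value strictly
#' exceeds the threshold (ties at exactly the threshold are retained).
#' Polarity bookkeeping is preserved.
#'
#' @param trials A `trial_set`.
#' @param cfg A [preprocess_config()].
#' @return The `trial_set` of retained trials, with attributes
#'   `n_rejected` and `rejected_idx`.
#' @export
reject_artifacts <- function(trials, cfg = preprocess_config()) {
  thr <- cfg$artifact_threshold
  mx <- .row_absmax_cpp(trials$trials)
  bad <- which(mx > thr)
  if (length(bad) == nrow(trials$trials))
    stop(sprintf("all trials exceed the +/-%g uV rejection threshold", thr))
  if (length(bad)) {
    trials$trials <- trials$trials[-bad, , drop = FALSE]
    trials$polarity <- trials$polarity[-bad]
  }
  trials$n_rejected <- length(bad)
  trials$rejected_idx <- bad
  trials
}

#' Averaged response container
#' @param samples Averaged voltage samples in uV.
#' @param sample_rate Sampling rate in Hz.
#' @param t0 Time of the first sample in ms.
#' @param n_sweeps_included Number of sweeps in the average.
#' @param provenance Configuration hash or other provenance string.
#' @return An object of class `average_response` (also a [waveform()]).
#' @export
average_response <- function(samples, sample_rate, t0, n_sweeps_included,
                             provenance = NA_character_) {
  w <- waveform(samples, sample_rate, t0, units = "uV")
  w$n_sweeps_included <- n_sweeps_included
  w$provenance <- provenance
  class(w) <- c("average_response", "waveform")
  w
}

#' Polarity addition and final averaging
#'
#' Selects `final_sweeps` retained trials (half per polarity, first retained
#' in presentation order) and forms the polarity-added average:
#' (mean of condensation trials + mean of rarefaction trials) / 2. Components
#' that invert with stimulus polarity (cochlear microphonic, stimulus
#' artifact) cancel; envelope-following components are preserved.
#'
#' @param trials A `trial_set` (after rejection).
#' @param cfg A [preprocess_config()].
#' @return An [average_response()].
#' @export
combine_polarities_and_average <- function(trials, cfg = preprocess_config()) {
  half <- cfg$final_sweeps / 2
  ic <- which(trials$polarity == "condensation")
  ir <- which(trials$polarity == "rarefaction")
  if (length(ic) < half || length(ir) < half)
    stop(sprintf(
      "insufficient balanced trials: need %d per polarity, have %d condensation and %d rarefaction",
      half, length(ic), length(ir)))
  ic <- ic[seq_len(half)]
  ir <- ir[seq_len(half)]
  avg <- (colMeans(trials$trials[ic, , drop = FALSE]) +
            colMeans(trials$trials[ir, , drop = FALSE])) / 2
  average_response(avg, trials$sample_rate, trials$t0, cfg$final_sweeps,
                   provenance = .hash(unclass(cfg)))
}

#' Full preprocessing chain
#'
#' Runs boost -> band-pass -> epoch/baseline -> artifact rejection ->
#' polarity-added averaging in that fixed order and returns both the final
#' average and the retained (filtered, epoched, rejected) trials needed by
#' the stability metric.
#'
#' @param trials A raw `trial_set`.
#' @param cfg A [preprocess_config()].
#' @return A list with `average` ([average_response()]), `retained`
#'   (`trial_set`), and `log` (per-stage trial counts).
#' @export
preprocess_trials <- function(trials, cfg = preprocess_config()) {
  n0 <- nrow(trials$trials)
  x <- low_freq_boost(trials, cfg)
  x <- bandpass(x, cfg)
  x <- epoch_baseline(x, cfg)
  x <- reject_artifacts(x, cfg)
  avg <- combine_polarities_and_average(x, cfg)
  list(
    average = avg,
    retained = x,
    log = list(n_presented = n0, n_rejected = x$n_rejected,
               n_retained = nrow(x$trials),
               n_averaged = avg$n_sweeps_included,
               config_hash = .hash(unclass(cfg)))
  )
}
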