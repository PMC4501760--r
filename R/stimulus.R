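#' Specification of the synthetic [da] syllable
#'
#' Parameters of the 170 ms consonant-vowel token used to evoke the FFR: a
#' voiced six-formant stop with a 5 ms voice onset time, a 50 ms /d/-to-/a/
#' formant transition, and a 120 ms steady vowel. The lower three formants
#' sweep linearly over the transition (F1 400-720 Hz, F2 1700-1240 Hz,
#' F3 2580-2500 Hz); F4-F6 and the 100 Hz fundamental are steady throughout.
#'
#' The token is rendered by a cascade of second-order resonators (one per
#' formant, fixed bandwidths) excited by a glottal impulse train plus a brief
#' noise burst at onset. Formant trajectories and durations are the contract;
#' perceptual fidelity is not.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param total_duration Total token duration in ms.
#' @param vot Voice onset time in ms (voicing begins here).
#' @param transition_duration Duration of the formant transition in ms.
#' @param vowel_duration Duration of the steady vowel in ms;
#'   `transition_duration + vowel_duration` must equal `total_duration`.
#' @param f0 Fundamental frequency in Hz.
#' @param formant_tracks 6 x 2 matrix of formant (start, end) frequencies in
#'   Hz; steady formants have start == end.
#' @param formant_bandwidths Resonator bandwidths in Hz, one per formant.
#' @param burst_duration Duration of the onset noise burst in ms.
#' @param burst_gain Linear gain of the burst relative to voicing.
#' @param voicing_gain Linear gain of the glottal source (0 silences it).
#'
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(sample_rate = 20000,
                          total_duration = 170,
                          vot = 5,
                          transition_duration = 50,
                          vowel_duration = 120,
                          f0 = 100,
                          formant_tracks = rbind(
                            F1 = c(400, 720),
                            F2 = c(1700, 1240),
                            F3 = c(2580, 2500),
                            F4 = c(3300, 3300),
                            F5 = c(3750, 3750),
                            F6 = c(4900, 4900)
                          ),
                          formant_bandwidths = c(60, 90, 150, 200, 250, 300),
                          burst_duration = 5,
                          burst_gain = 0.3,
                          voicing_gain = 1) {
  formant_tracks <- as.matrix(formant_tracks)
  stopifnot(ncol(formant_tracks) == 2, nrow(formant_tracks) >= 1)
  if (abs(transition_duration + vowel_duration - total_duration) > 1e-9)
    stop("transition_duration + vowel_duration must equal total_duration")
  if (length(formant_bandwidths) != nrow(formant_tracks))
    stop("one bandwidth per formant track is required")
  nyq <- sample_rate / 2
  over <- which(apply(formant_tracks, 1, max) >= nyq)
  if (length(over)) {
    nm <- rownames(formant_tracks)[over]
    if (is.null(nm)) nm <- paste0("track ", over)
    stop(sprintf("formant track(s) %s at or above the Nyquist frequency (%g Hz)",
                 paste(nm, collapse = ", "), nyq))
  }
  structure(list(
    sample_rate = sample_rate, total_duration = total_duration, vot = vot,
    transition_duration = transition_duration, vowel_duration = vowel_duration,
    f0 = f0, formant_tracks = formant_tracks,
    formant_bandwidths = formant_bandwidths,
    burst_duration = burst_duration, burst_gain = burst_gain,
    voicing_gain = voicing_gain
  ), class = "stimulus_spec")
}

# One Klatt-style digital resonator with a per-sample centre frequency.
# y[n] = A x[n] + B y[n-1] + C y[n-2]; C = -exp(-2 pi b T),
# B = 2 exp(-pi b T) cos(2 pi f T), A = 1 - B - C (unity DC-ish gain).
#' @noRd
.resonate <- function(x, freq, bw, sample_rate) {
  T <- 1 / sample_rate
  C <- -exp(-2 * pi * bw * T)
  Bc <- 2 * exp(-pi * bw * T)
  B <- Bc * cos(2 * pi * freq * T)
  A <- 1 - B - C
  n <- length(x)
  y <- numeric(n)
  y1 <- 0; y2 <- 0
  for (i in seq_len(n)) {
    yi <- A[i] * x[i] + B[i] * y1 + C * y2
    y2 <- y1; y1 <- yi
    y[i] <- yi
  }
  y
}

#' Synthesize the [da] token
#'
#' Renders the consonant-vowel syllable described by a [stimulus_spec()]:
#' a glottal impulse train at `f0` starting at the voice onset time, plus a
#' short deterministic noise burst at onset, passed through a cascade of
#' second-order formant resonators whose lower-formant centre frequencies
#' sweep linearly over the transition and then hold. The result is peak
#' normalized to |amplitude| <= 1.
#'
#' @param spec A [stimulus_spec()].
#' @return A [waveform()] with exactly
#'   `round(total_duration * sample_rate / 1000)` samples.
#' @export
#' @examples
#' da <- synth_da(stimulus_spec())
#' length(da$samples)  # 3400 at the 20 kHz default
synth_da <- function(spec = stimulus_spec()) {
  sr <- spec$sample_rate
  n <- .ms_to_samples(spec$total_duration, sr)
  t_ms <- 1000 * (seq_len(n) - 1) / sr

  # Glottal source: unit impulses every 1/f0 s, first at the voice onset time.
  src <- numeric(n)
  if (spec$voicing_gain != 0) {
    pulse_t <- seq(spec$vot, spec$total_duration, by = 1000 / spec$f0)
    idx <- .ms_to_samples(pulse_t, sr) + 1
    idx <- idx[idx >= 1 & idx <= n]
    src[idx] <- spec$voicing_gain
  }

  # Onset burst: fixed-seed noise so synthesis is deterministic.
  if (spec$burst_gain != 0 && spec$burst_duration > 0) {
    nb <- min(n, .ms_to_samples(spec$burst_duration, sr))
    burst <- .with_seed(760417L, rnorm(nb))
    src[seq_len(nb)] <- src[seq_len(nb)] +
      spec$burst_gain * burst * exp(-(seq_len(nb) - 1) / (0.3 * nb))
  }

  # Cascade of resonators; F tracks interpolate linearly over the transition.
  frac <- pmin(t_ms / spec$transition_duration, 1)
  y <- src
  for (k in seq_len(nrow(spec$formant_tracks))) {
    f <- spec$formant_tracks[k, 1] +
      (spec$formant_tracks[k, 2] - spec$formant_tracks[k, 1]) * frac
    y <- .resonate(y, f, spec$formant_bandwidths[k], sr)
  }

  peak <- max(abs(y))
  if (peak > 0) y <- y / peak
  waveform(y, sr, t0 = 0, units = "au")
}

#' Specification of the babble masker surrogate
#'
#' Stand-in for a multi-talker babble track: several independent
#' speech-shaped noise streams, each amplitude-modulated at a syllabic rate,
#' summed. The loop is rendered with circular spectral shaping and an
#' integer number of modulation cycles so that tiling it end-to-end is
#' continuous (no splice clicks).
#'
#' @param n_talkers Number of independent streams.
#' @param n_female Number of streams given the higher ("female") spectral
#'   knee; the rest use the lower knee.
#' @param loop_duration Loop length in ms.
#' @param modulation_rate Syllabic amplitude-modulation rate in Hz.
#' @param seed RNG seed for the noise streams and modulation phases.
#' @return A list of class `babble_spec`.
#' @export
babble_spec <- function(n_talkers = 6, n_female = 3, loop_duration = 4000,
                        modulation_rate = 4, seed = NULL) {
  stopifnot(n_talkers >= 1, n_female >= 0, n_female <= n_talkers,
            loop_duration > 0, modulation_rate >= 0)
  structure(list(
    n_talkers = n_talkers, n_female = n_female,
    loop_duration = loop_duration, modulation_rate = modulation_rate,
    seed = seed
  ), class = "babble_spec")
}

#' Synthesize a looping multi-talker babble surrogate
#'
#' @param spec A [babble_spec()].
#' @param sample_rate Output sampling rate in Hz.
#' @param out_duration Output duration in ms; the rendered loop is tiled and
#'   trimmed, so any `out_duration` longer than the loop repeats it exactly.
#' @return A [waveform()] normalized to unit RMS.
#' @export
synth_babble <- function(spec, sample_rate, out_duration) {
  stopifnot(inherits(spec, "babble_spec"))
  if (out_duration <= 0) stop("out_duration must be positive")
  n_loop <- .ms_to_samples(spec$loop_duration, sample_rate)
  loop <- .with_seed(spec$seed, {
    freqs <- c(0, seq_len(n_loop - 1))
    freqs <- pmin(freqs, n_loop - freqs) * sample_rate / n_loop  # |f| per bin
    t <- (seq_len(n_loop) - 1) / sample_rate
    n_cycles <- max(1, round(spec$modulation_rate * spec$loop_duration / 1000))
    total <- numeric(n_loop)
    for (k in seq_len(spec$n_talkers)) {
      knee <- if (k <= spec$n_female) 625 else 500
      gain <- ifelse(freqs < 100, freqs / 100,
                     ifelse(freqs <= knee, 1, knee / freqs))
      z <- fft(rnorm(n_loop))
      stream <- Re(fft(z * gain, inverse = TRUE)) / n_loop
      phase <- runif(1, 0, 2 * pi)
      env <- 1 + 0.5 * sin(2 * pi * n_cycles * t / (n_loop / sample_rate) + phase)
      total <- total + stream * env
    }
    total
  })
  n_out <- .ms_to_samples(out_duration, sample_rate)
  out <- rep_len(loop, n_out)
  waveform(out / rms(out), sample_rate, t0 = 0, units = "au")
}

#' Mix a target into noise at a specified SNR
#'
#' Rescales the noise so that the RMS of the target over its full duration,
#' relative to the RMS of the concurrent noise segment, equals
#' `10^(snr_db/20)`, then sums the two into a single channel of the target's
#' length.
#'
#' @param target Target [waveform()].
#' @param noise Noise [waveform()] at the same sampling rate, at least as
#'   long as the target.
#' @param snr_db Desired signal-to-noise ratio in dB.
#' @return A [waveform()] of the same length as `target`.
#' @export
mix_at_snr <- function(target, noise, snr_db) {
  stopifnot(inherits(target, "waveform"), inherits(noise, "waveform"))
  if (target$sample_rate != noise$sample_rate)
    stop("target and noise must share a sampling rate")
  nt <- length(target$samples)
  if (length(noise$samples) < nt)
    stop("noise must be at least as long as the target")
  seg <- noise$samples[seq_len(nt)]
  rt <- rms(target); rn <- rms(seg)
  if (rt == 0) stop("silent target: SNR undefined")
  if (rn == 0) stop("silent noise: SNR undefined")
  scale <- (rt / rn) * 10^(-snr_db / 20)
  waveform(target$samples + scale * seg, target$sample_rate,
           t0 = target$t0, units = target$units)
}

#' Fundamental periodicity by autocorrelation
#'
#' Estimates the fundamental frequency of a quasi-periodic segment as the
#' reciprocal of the lag of the largest strict local maximum of the
#' normalized autocorrelation over positive lags.
#'
#' @param w A [waveform()].
#' @param from_ms,to_ms Segment to analyse, in ms on the waveform's time axis.
#' @param max_lag_ms Largest lag searched, in ms.
#' @return A list with `f0_hz`, `lag_ms`, and the autocorrelation sequence.
#' @export
fundamental_periodicity <- function(w, from_ms = 60, to_ms = 170,
                                    max_lag_ms = 25) {
  idx <- .window_idx(length(w$samples), w$sample_rate, w$t0, from_ms, to_ms)
  x <- w$samples[idx]
  x <- x - mean(x)
  n <- length(x)
  max_lag <- min(n - 2, .ms_to_samples(max_lag_ms, w$sample_rate))
  # autocorrelation via FFT with zero padding (linear, not circular)
  nfft <- 2^ceiling(log2(2 * n))
  X <- fft(c(x, numeric(nfft - n)))
  ac <- Re(fft(X * Conj(X), inverse = TRUE))[seq_len(max_lag + 1)]
  ac <- ac / ac[1]
  lag <- seq(0, max_lag)
  interior <- 2:max_lag
  is_max <- ac[interior] > ac[interior - 1] & ac[interior] > ac[interior + 1]
  cand <- interior[is_max]
  if (!length(cand)) stop("no local autocorrelation maximum in the lag range")
  best <- cand[which.max(ac[cand])]
  lag_ms <- 1000 * (best - 1) / w$sample_rate
  list(f0_hz = 1000 / lag_ms, lag_ms = lag_ms, acf = ac, lags = lag)
}
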