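#' Peak-picking configuration
#'
#' @param nominal_latencies Nominal transition peak latencies in ms; a peak
#'   found near 21 ms is reported as "Peak 21", and so on.
#' @param search_halfwidth Half-width (ms) of the search window around each
#'   nominal latency.
#' @param analysis_window Analysis window in ms (consonant transition).
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(nominal_latencies = c(21, 31, 41, 51),
                        search_halfwidth = 2,
                        analysis_window = c(20, 60)) {
  if (any(diff(nominal_latencies) <= 2 * search_halfwidth))
    stop("peak search windows overlap")
  structure(list(nominal_latencies = nominal_latencies,
                 search_halfwidth = search_halfwidth,
                 analysis_window = analysis_window),
            class = "peak_config")
}

#' Split-half stability configuration
#'
#' @param n_pairs Number of random half-split pairs (default 300).
#' @param window Correlation window in ms.
#' @param seed RNG seed for the random partitions.
#' @return A list of class `stability_config`.
#' @export
stability_config <- function(n_pairs = 300, window = c(20, 60), seed = NULL) {
  if (n_pairs < 1) stop("n_pairs must be at least 1")
  structure(list(n_pairs = n_pairs, window = window, seed = seed),
            class = "stability_config")
}

#' Spectral-amplitude configuration
#'
#' @param window FFT window in ms (consonant transition).
#' @param ramp Raised-cosine (Hanning) on/off ramp duration in ms, applied
#'   at both window edges with a flat top between them.
#' @param harmonics Harmonic centre frequencies in Hz.
#' @param bin_halfwidth Half-width in Hz of the bin averaged around each
#'   centre (40 Hz bins = centre +/- 20 Hz).
#' @param fft_length FFT length in samples (zero-padded); NULL chooses the
#'   smallest power of two >= 4096 that holds the segment.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(window = c(20, 60), ramp = 10,
                            harmonics = c(400, 500, 600, 700),
                            bin_halfwidth = 20, fft_length = NULL) {
  if (ramp > (window[2] - window[1]) / 2)
    stop("ramp longer than half the analysis window")
  structure(list(window = window, ramp = ramp, harmonics = harmonics,
                 bin_halfwidth = bin_halfwidth, fft_length = fft_length),
            class = "spectral_config")
}

#' Detect transition peaks by local-maximum search
#'
#' For each nominal latency, finds the largest strict local maximum (a
#' sample exceeding both neighbours) within nominal +/- `search_halfwidth`
#' ms, clipped to the analysis window; ties are broken by the earliest
#' latency. A window with no local maximum yields `NA` and is flagged.
#' Replaces manual peak editing with a deterministic, auditable picker.
#'
#' @param avg An [average_response()] (or any [waveform()]).
#' @param cfg A [peak_config()].
#' @return Named numeric vector of latencies in ms (e.g. `peak_latency_21`),
#'   `NA` where missing, with attribute `missing` naming unfound peaks.
#' @export
detect_peaks <- function(avg, cfg = peak_config()) {
  x <- avg$samples
  t <- time_axis(avg)
  n <- length(x)
  out <- setNames(rep(NA_real_, length(cfg$nominal_latencies)),
                  paste0("peak_latency_", cfg$nominal_latencies))
  for (j in seq_along(cfg$nominal_latencies)) {
    nom <- cfg$nominal_latencies[j]
    lo <- max(nom - cfg$search_halfwidth, cfg$analysis_window[1])
    hi <- min(nom + cfg$search_halfwidth, cfg$analysis_window[2])
    idx <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
    idx <- idx[idx > 1 & idx < n]
    if (!length(idx)) next
    is_max <- x[idx] > x[idx - 1] & x[idx] > x[idx + 1]
    cand <- idx[is_max]
    if (!length(cand)) next
    out[j] <- t[cand[which.max(x[cand])]]  # which.max takes earliest on ties
  }
  attr(out, "missing") <- names(out)[is.na(out)]
  out
}

#' Trial-by-trial response stability
#'
#' Repeats `n_pairs` times: randomly partition the retained trials into two
#' disjoint, polarity-balanced halves; form each half's polarity-added
#' sub-average; compute the Pearson correlation between the two sub-averages
#' over the analysis window. Reports the mean correlation and its Fisher z
#' (atanh, clipped away from +/-1). Deterministic for a fixed seed.
#'
#' @param trials A retained (filtered, epoched, artifact-rejected)
#'   `trial_set`.
#' @param cfg A [stability_config()].
#' @return A list with `stability_r`, `stability_z`, `n_trials_used`,
#'   `clipped` (TRUE if the Fisher transform was clipped), and the per-pair
#'   correlations `r_pairs`.
#' @export
response_stability <- function(trials, cfg = stability_config()) {
  idx <- .window_idx(ncol(trials$trials), trials$sample_rate, trials$t0,
                     cfg$window[1], cfg$window[2])
  ic <- which(trials$polarity == "condensation")
  ir <- which(trials$polarity == "rarefaction")
  if (length(ic) %% 2 == 1) ic <- ic[-length(ic)]
  if (length(ir) %% 2 == 1) ir <- ir[-length(ir)]
  if (length(ic) < 2 || length(ir) < 2)
    stop("need at least two retained trials per polarity")
  Wc <- t(trials$trials[ic, idx, drop = FALSE])  # window x trials
  Wr <- t(trials$trials[ir, idx, drop = FALSE])
  mC <- length(ic); mR <- length(ir)
  P <- cfg$n_pairs
  .with_seed(cfg$seed, {
    SC <- matrix(0, mC, P); SR <- matrix(0, mR, P)
    for (p in seq_len(P)) {
      SC[sample.int(mC, mC / 2), p] <- 1
      SR[sample.int(mR, mR / 2), p] <- 1
    }
    sumCA <- Wc %*% SC; sumRA <- Wr %*% SR
    meanA <- (sumCA / (mC / 2) + sumRA / (mR / 2)) / 2
    meanB <- ((rowSums(Wc) - sumCA) / (mC / 2) +
                (rowSums(Wr) - sumRA) / (mR / 2)) / 2
    a <- sweep(meanA, 2, colMeans(meanA))
    b <- sweep(meanB, 2, colMeans(meanB))
    r <- colSums(a * b) / sqrt(colSums(a^2) * colSums(b^2))
    rbar <- mean(r)
    clipped <- abs(rbar) >= 1 - .FISHER_EPS
    z <- atanh(min(max(rbar, -1 + .FISHER_EPS), 1 - .FISHER_EPS))
    list(stability_r = rbar, stability_z = z,
         n_trials_used = mC + mR, clipped = clipped, r_pairs = r)
  })
}

#' First-formant spectral amplitudes
#'
#' Extracts the analysis window from the averaged response, applies
#' raised-cosine on/off ramps, zero-pads, and computes the single-sided
#' amplitude spectrum in uV (2|X|/N with N the un-padded segment length).
#' Each harmonic amplitude is the mean over its 40 Hz bin (centre +/- 20 Hz);
#' their average indexes first-formant coding.
#'
#' @param avg An [average_response()] (or any [waveform()]).
#' @param cfg A [spectral_config()].
#' @return Named numeric: `h4`, `h5`, `h6`, `h7`, `f1_mean_amplitude` (uV).
#' @export
spectral_amplitudes <- function(avg, cfg = spectral_config()) {
  idx <- .window_idx(length(avg$samples), avg$sample_rate, avg$t0,
                     cfg$window[1], cfg$window[2])
  seg <- avg$samples[idx]
  n <- length(seg)
  t_rel <- (seq_len(n) - 1) * 1000 / avg$sample_rate
  seg <- seg * .ramped_window(t_rel, 0, t_rel[n], cfg$ramp)
  nfft <- cfg$fft_length
  if (is.null(nfft)) nfft <- max(4096, 2^ceiling(log2(n)))
  if (nfft < n) stop("fft_length shorter than the analysis segment")
  amp <- 2 * Mod(fft(c(seg, numeric(nfft - n)))) / n
  freq <- (seq_len(nfft) - 1) * avg$sample_rate / nfft
  h <- vapply(cfg$harmonics, function(fc) {
    mean(amp[freq >= fc - cfg$bin_halfwidth - 1e-9 &
               freq <= fc + cfg$bin_halfwidth + 1e-9])
  }, numeric(1))
  names(h) <- paste0("h", cfg$harmonics / 100)
  c(h, f1_mean_amplitude = mean(h))
}

#' Compute the nine neural predictors for one child
#'
#' Bundles [detect_peaks()], [spectral_amplitudes()] (both on the final
#' average) and [response_stability()] (on the retained trials) into the
#' nine-predictor row used by the scoring model. Behavioral data never
#' enters this computation.
#'
#' @param avg An [average_response()].
#' @param trials The retained `trial_set` from the same recording.
#' @param peak_cfg,stab_cfg,spec_cfg Stage configurations.
#' @return A one-row tibble of class `neural_metrics` with columns
#'   `peak_latency_21/31/41/51`, `h4`-`h7`, `f1_mean_amplitude`,
#'   `stability_r`, `stability_z`.
#' @export
compute_metrics <- function(avg, trials,
                            peak_cfg = peak_config(),
                            stab_cfg = stability_config(),
                            spec_cfg = spectral_config()) {
  pk <- detect_peaks(avg, peak_cfg)
  sp <- spectral_amplitudes(avg, spec_cfg)
  st <- response_stability(trials, stab_cfg)
  out <- tibble::as_tibble(c(as.list(pk), as.list(sp),
                             list(stability_r = st$stability_r,
                                  stability_z = st$stability_z)))
  attr(out, "config_hash") <- .hash(list(unclass(peak_cfg),
                                         unclass(stab_cfg),
                                         unclass(spec_cfg)))
  attr(out, "missing_peaks") <- attr(pk, "missing")
  class(out) <- c("neural_metrics", class(out))
  out
}

#' The nine neural predictor column names
#' @return Character vector in model order.
#' @export
neural_predictors <- function() {
  c("peak_latency_21", "peak_latency_31", "peak_latency_41",
    "peak_latency_51", "h4", "h5", "h6", "h7", "stability_z")
}
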