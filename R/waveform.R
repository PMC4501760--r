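#' Sampled waveform container
#'
#' A minimal container for a regularly sampled acoustic or neural signal:
#' the sample values, the sampling rate in Hz, the time (ms) of the first
#' sample relative to stimulus onset, and a units label.
#'
#' @param samples Numeric vector of sample values; must be finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in ms relative to stimulus onset.
#' @param units Units label, e.g. `"au"` (acoustic, arbitrary) or `"uV"`.
#'
#' @return An object of class `waveform`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 100 * (0:199) / 2000), sample_rate = 2000)
#' duration_ms(w)
waveform <- function(samples, sample_rate, t0 = 0, units = "au") {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = samples, sample_rate = sample_rate, t0 = t0, units = units),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform> %d samples @ %g Hz (%.1f ms), t0 = %g ms, units = %s\n",
    length(x$samples), x$sample_rate, duration_ms(x), x$t0, x$units
  ))
  invisible(x)
}

#' Duration of a waveform in milliseconds
#' @param w A [waveform()].
#' @return Duration in ms.
#' @export
duration_ms <- function(w) 1000 * length(w$samples) / w$sample_rate

#' Sample times of a waveform in milliseconds
#' @param w A [waveform()].
#' @return Numeric vector of times (ms) aligned with `w$samples`.
#' @export
time_axis <- function(w) w$t0 + 1000 * (seq_along(w$samples) - 1) / w$sample_rate

#' Root-mean-square amplitude
#' @param x Numeric vector or [waveform()].
#' @return RMS value.
#' @export
rms <- function(x) {
  if (inherits(x, "waveform")) x <- x$samples
  sqrt(mean(x^2))
}

#' @noRd
.ms_to_samples <- function(ms, sample_rate) round(ms * sample_rate / 1000)

# Index range (1-based, inclusive) of a [from, to] ms window within a signal
# whose first sample sits at t0 ms.
#' @noRd
.window_idx <- function(n, sample_rate, t0, from_ms, to_ms) {
  t <- t0 + 1000 * (seq_len(n) - 1) / sample_rate
  which(t >= from_ms - 1e-9 & t <= to_ms + 1e-9)
}
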