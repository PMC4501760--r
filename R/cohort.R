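#' Ground-truth response template for one child
#'
#' The generative description of a child's FFR: latencies and amplitudes of
#' the four transition peaks (nominal 21/31/41/51 ms), first-formant harmonic
#' amplitudes at 400-700 Hz over the 20-60 ms consonant-transition window,
#' an envelope-following 100 Hz component, and an optional stimulus-artifact
#' component that inverts with stimulus polarity.
#'
#' @param peak_latencies Named numeric, ms, strictly increasing; one per
#'   nominal peak (p21, p31, p41, p51).
#' @param peak_amplitudes Peak amplitudes in uV (>= 0).
#' @param harmonic_amplitudes Amplitudes in uV at 400/500/600/700 Hz.
#' @param envelope_f0_amplitude Amplitude in uV of the 100 Hz envelope
#'   component (sign-invariant across stimulus polarity).
#' @param stim_artifact_amplitude Amplitude in uV of a 100 Hz component that
#'   flips sign with stimulus polarity (cancelled by polarity addition).
#' @param sample_rate Sampling rate in Hz of rendered trials.
#' @param epoch_window Epoch limits in ms, `c(start, end)` with onset at 0.
#' @return A list of class `response_template`.
#' @export
response_template <- function(peak_latencies = c(p21 = 21.4, p31 = 31.3,
                                                 p41 = 41.2, p51 = 51.1),
                              peak_amplitudes = c(0.60, 0.55, 0.50, 0.45),
                              harmonic_amplitudes = c(h4 = 0.10, h5 = 0.09,
                                                      h6 = 0.07, h7 = 0.05),
                              envelope_f0_amplitude = 0.15,
                              stim_artifact_amplitude = 0,
                              sample_rate = 8000,
                              epoch_window = c(-40, 210)) {
  if (any(diff(peak_latencies) <= 0))
    stop("peak latencies must be strictly increasing")
  if (any(c(peak_amplitudes, harmonic_amplitudes,
            envelope_f0_amplitude, stim_artifact_amplitude) < 0))
    stop("amplitudes must be non-negative")
  if (any(peak_latencies <= epoch_window[1]) ||
      any(peak_latencies >= epoch_window[2]))
    stop("peak latencies must lie inside the epoch window")
  structure(list(
    peak_latencies = peak_latencies, peak_amplitudes = peak_amplitudes,
    harmonic_amplitudes = harmonic_amplitudes,
    envelope_f0_amplitude = envelope_f0_amplitude,
    stim_artifact_amplitude = stim_artifact_amplitude,
    sample_rate = sample_rate, epoch_window = epoch_window
  ), class = "response_template")
}

# Raised-cosine on/off ramped window restricted to [from, to] ms.
#' @noRd
.ramped_window <- function(t_ms, from, to, ramp) {
  w <- numeric(length(t_ms))
  inside <- t_ms >= from & t_ms <= to
  w[inside] <- 1
  if (ramp > 0) {
    up <- inside & t_ms < from + ramp
    dn <- inside & t_ms > to - ramp
    w[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - from) / ramp))
    w[dn] <- 0.5 * (1 - cos(pi * (to - t_ms[dn]) / ramp))
  }
  w
}

#' Render the deterministic components of a response template
#'
#' Transient peaks are Gaussian-windowed deflections (sigma 0.35 ms, about
#' 1 ms wide) so that strict local-maximum picking is well defined; harmonic
#' and envelope components are ramped sinusoids over the transition window.
#'
#' @param template A [response_template()].
#' @return A list with `invariant` (uV, polarity-invariant part), `artifact`
#'   (uV, polarity-flipping part), and the time axis `t_ms`.
#' @export
render_template <- function(template) {
  sr <- template$sample_rate
  ep <- template$epoch_window
  n <- .ms_to_samples(ep[2] - ep[1], sr)
  t <- ep[1] + 1000 * (seq_len(n) - 1) / sr
  sigma <- 0.35  # ms
  inv <- numeric(n)
  for (j in seq_along(template$peak_latencies)) {
    inv <- inv + template$peak_amplitudes[j] *
      exp(-(t - template$peak_latencies[j])^2 / (2 * sigma^2))
  }
  harm_f <- c(400, 500, 600, 700)
  w_trans <- .ramped_window(t, 20, 60, 5)
  for (j in seq_along(harm_f)) {
    inv <- inv + template$harmonic_amplitudes[j] * w_trans *
      sin(2 * pi * harm_f[j] * (t - 20) / 1000)
  }
  w_env <- .ramped_window(t, 20, 170, 5)
  inv <- inv + template$envelope_f0_amplitude * w_env *
    sin(2 * pi * 100 * (t - 20) / 1000)
  art <- template$stim_artifact_amplitude *
    .ramped_window(t, 0, 170, 5) * sin(2 * pi * 100 * t / 1000)
  list(invariant = inv, artifact = art, t_ms = t)
}

#' Cohort simulation parameters
#'
#' Defines a simulated study cohort: demographics, per-child recording
#' parameters, and the effect map linking a latent preliteracy ability to
#' both the neural response template and the behavioral scores. The defaults
#' mirror the preschool protocol (4,200 sweeps per child, alternating
#' polarities, epoch -40 to 210 ms) with demographics matching a cohort of
#' 37 four-year-olds (mean age 54.41 months, SD 3.56, 21/37 female).
#'
#' @param n_children Number of children.
#' @param age_months `c(mean, sd)` of age in months.
#' @param sex_ratio Proportion female (dummy-coded male = 0, female = 1).
#' @param iq `c(mean, sd)` of the non-verbal IQ scale score.
#' @param n_trials_per_child Sweeps presented per child (even).
#' @param artifact_rate Per-trial probability of an injected high-amplitude
#'   artifact exceeding the +/-35 uV rejection threshold.
#' @param jitter_sd Trial-level latency jitter SD in ms.
#' @param noise_sd Additive noise SD in uV (1/f-weighted spectrum).
#' @param noise_exponent Spectral exponent of the additive noise
#'   (power ~ 1/f^exponent above `noise_knee_hz`).
#' @param noise_knee_hz Frequency below which the noise spectrum is flat.
#' @param sample_rate Sampling rate of simulated recordings in Hz.
#' @param epoch_window Epoch limits in ms.
#' @param effect_map Named list of weights linking latent ability (SD units)
#'   to template parameters and behavior; see Details.
#' @param reliability Test-retest reliability of behavioral scores in (0, 1].
#' @param ld_fraction If non-NULL, fraction of children labelled LD by a
#'   noisy threshold on latent ability (`group_overlap_sd` of label noise).
#' @param group_overlap_sd SD of the label noise used for group assignment.
#' @param seed RNG seed; the cohort is deterministic given the seed.
#'
#' @details The effect map entries are: `latency_w` (ms per ability SD;
#' negative means earlier peaks with higher ability) and `latency_sd`
#' (child-level residual, ms); `amplitude_w`/`amplitude_sd` (uV) for peak
#' amplitudes; `harmonic_w`/`harmonic_sd` (uV) for the four harmonic
#' amplitudes; `f0_w`/`f0_sd` (uV) for the envelope component;
#' `noise_mult` and `jitter_mult` (log-scale multipliers: child noise SD is
#' `noise_sd * exp(noise_mult * ability)`); `behavior_w` (score points per
#' ability SD) and `behavior_age_w` (points per month of age).
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_children = 37,
                        age_months = c(54.41, 3.56),
                        sex_ratio = 21 / 37,
                        iq = c(10, 3),
                        n_trials_per_child = 4200,
                        artifact_rate = 0.02,
                        jitter_sd = 0.25,
                        noise_sd = 0.5,
                        noise_exponent = 1,
                        noise_knee_hz = 10,
                        sample_rate = 8000,
                        epoch_window = c(-40, 210),
                        effect_map = default_effect_map(),
                        reliability = 0.90,
                        ld_fraction = NULL,
                        group_overlap_sd = 0.8,
                        seed = NULL) {
  if (n_trials_per_child %% 2 != 0) stop("n_trials_per_child must be even")
  if (artifact_rate < 0 || artifact_rate >= 1)
    stop("artifact_rate must be in [0, 1)")
  if (reliability <= 0 || reliability > 1)
    stop("reliability must be in (0, 1]")
  structure(list(
    n_children = n_children, age_months = age_months, sex_ratio = sex_ratio,
    iq = iq, n_trials_per_child = n_trials_per_child,
    artifact_rate = artifact_rate, jitter_sd = jitter_sd,
    noise_sd = noise_sd, noise_exponent = noise_exponent,
    noise_knee_hz = noise_knee_hz, sample_rate = sample_rate,
    epoch_window = epoch_window, effect_map = effect_map,
    reliability = reliability, ld_fraction = ld_fraction,
    group_overlap_sd = group_overlap_sd, seed = seed
  ), class = "cohort_spec")
}

#' Default ability-to-parameter effect map
#'
#' Weights chosen so that, at n = 37, simulated brain-behavior correlations
#' fall in the 0.5-0.8 range typical of the metrics modelled here.
#' @return Named list of weights; see [cohort_spec()].
#' @export
default_effect_map <- function() {
  list(
    latency_w = -0.3, latency_sd = 0.20,
    amplitude_w = 0.05, amplitude_sd = 0.04,
    harmonic_w = 0.02, harmonic_sd = 0.012,
    f0_w = 0.03, f0_sd = 0.02,
    noise_mult = -0.15, jitter_mult = -0.15,
    behavior_w = 4, behavior_age_w = 0.3
  )
}

#' Generate a child's response template from latent ability
#'
#' Template parameters are affine functions of latent ability plus
#' child-level Gaussian noise drawn from the current RNG stream (seed it
#' via [generate_cohort()] or `set.seed()`). Higher ability maps to earlier
#' peaks and larger harmonic amplitudes under the default effect map.
#'
#' @param latent_ability Latent preliteracy ability in SD units.
#' @param spec A [cohort_spec()].
#' @return A [response_template()].
#' @export
generate_template <- function(latent_ability, spec) {
  em <- spec$effect_map
  base <- response_template(sample_rate = spec$sample_rate,
                            epoch_window = spec$epoch_window)
  lat <- base$peak_latencies + em$latency_w * latent_ability +
    rnorm(4, 0, em$latency_sd)
  amp <- pmax(base$peak_amplitudes + em$amplitude_w * latent_ability +
                rnorm(4, 0, em$amplitude_sd), 0.05)
  harm <- pmax(base$harmonic_amplitudes + em$harmonic_w * latent_ability +
                 rnorm(4, 0, em$harmonic_sd), 0.001)
  f0a <- max(base$envelope_f0_amplitude + em$f0_w * latent_ability +
               rnorm(1, 0, em$f0_sd), 0.001)
  response_template(
    peak_latencies = lat, peak_amplitudes = amp, harmonic_amplitudes = harm,
    envelope_f0_amplitude = f0a,
    sample_rate = spec$sample_rate, epoch_window = spec$epoch_window
  )
}

# Shift a vector by k samples (positive = later), zero filled.
#' @noRd
.shift_vec <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k > 0) c(numeric(k), x[seq_len(n - k)]) else c(x[(-k + 1):n], numeric(-k))
}

# n_rows independent noise rows of length n_cols with spectral shape
# `gain` (per-FFT-bin linear gain on unit-variance white noise), scaled by
# sd_rows. Synthesized directly in the frequency domain: a non-Hermitian
# complex Gaussian spectrum inverts to a complex series whose real and
# imaginary parts are two independent real noise streams with the target
# spectrum, so one inverse FFT yields two rows.
#' @noRd
.colored_noise <- function(n_rows, n_cols, sd_rows, gain) {
  if (all(sd_rows == 0)) return(matrix(0, n_rows, n_cols))
  half <- ceiling(n_rows / 2)
  # var(Re x_n) = (1/N^2) sum_k var(Re Z_k); with per-component sd
  # gain_k * sqrt(N) and mean(gain^2) = 1 this gives unit variance.
  sdv <- gain * sqrt(n_cols)
  Z <- matrix(complex(real = rnorm(n_cols * half),
                      imaginary = rnorm(n_cols * half)), n_cols, half) * sdv
  y <- mvfft(Z, inverse = TRUE) / n_cols
  out <- matrix(0, n_rows, n_cols)
  odd <- seq(1, n_rows, by = 2)
  even <- seq(2, n_rows, by = 2)
  out[odd, ] <- t(Re(y))[seq_along(odd), , drop = FALSE]
  if (length(even)) out[even, ] <- t(Im(y))[seq_along(even), , drop = FALSE]
  out * sd_rows
}

# Spectral shape of the additive EEG-like noise floor: flat below the knee,
# 1/f^(exponent/2) amplitude above it, normalised to unit output variance.
#' @noRd
.noise_gain <- function(n_cols, sample_rate, exponent, knee_hz) {
  freqs <- c(0, seq_len(n_cols - 1))
  freqs <- pmin(freqs, n_cols - freqs) * sample_rate / n_cols
  gain <- ifelse(freqs < knee_hz, 1,
                 (pmax(freqs, 1e-6) / knee_hz)^(-exponent / 2))
  gain / sqrt(mean(gain^2))
}

# Gain of the online acquisition high-pass emulated at generation time
# (20 dB/decade below 100 Hz, floored at 0.1 Hz); the offline low-frequency
# boost is its exact inverse.
#' @noRd
.acquisition_gain <- function(freq_hz) pmin(1, pmax(freq_hz, 0.1) / 100)

#' Generate an epoched trial set from a response template
#'
#' Each trial is the rendered template shifted by Gaussian latency jitter
#' (rounded to whole samples), with the polarity-flipping artifact component
#' applied according to the trial's alternating polarity, plus additive
#' 1/f-weighted noise. A fraction `artifact_rate` of trials receives an
#' injected in-band excursion exceeding the +/-35 uV rejection threshold.
#'
#' @param template A [response_template()].
#' @param spec A [cohort_spec()]; `jitter_sd` and `noise_sd` may be
#'   overridden per child via `jitter_sd`/`noise_sd` arguments.
#' @param seed RNG seed for this child's recording.
#' @param jitter_sd,noise_sd Optional per-child overrides (ms, uV).
#' @return A `trial_set`: list with `trials` (n_trials x n_samples matrix,
#'   uV), `polarity` (alternating `"condensation"`/`"rarefaction"`),
#'   `sample_rate`, `t0` (ms), `epoch_window`, and `artifact_trials`
#'   (indices of trials with injected excursions).
#' @export
generate_trials <- function(template, spec, seed = NULL,
                            jitter_sd = spec$jitter_sd,
                            noise_sd = spec$noise_sd) {
  stopifnot(inherits(template, "response_template"))
  n_tr <- spec$n_trials_per_child
  if (n_tr %% 2 != 0) stop("trial count must be even")
  rend <- render_template(template)
  n <- length(rend$invariant)
  sr <- template$sample_rate
  ep <- template$epoch_window
  .with_seed(seed, {
    jit <- rnorm(n_tr, 0, jitter_sd)
    if (any(min(template$peak_latencies) + jit < ep[1]) ||
        any(max(template$peak_latencies) + jit > ep[2]))
      stop("latency jitter pushes peaks outside the epoch window")
    shift <- as.integer(round(jit * sr / 1000))
    pol <- rep(c(1, -1), length.out = n_tr)  # condensation, rarefaction, ...
    # The online acquisition high-pass (20 dB/decade below 100 Hz, floored
    # at 0.1 Hz) is part of data generation: it shapes both the noise floor
    # and the evoked components before the offline chain sees them; the
    # offline low-frequency boost is its exact inverse.
    gain <- .noise_gain(n, sr, spec$noise_exponent, spec$noise_knee_hz) *
      .acquisition_gain(pmin((seq_len(n) - 1), n - (seq_len(n) - 1)) * sr / n)
    trials <- .colored_noise(n_tr, n, noise_sd, gain)
    comp <- .apply_freq_gain(rbind(rend$invariant, rend$artifact), sr,
                             .acquisition_gain)
    for (k in unique(shift)) {
      rows <- which(shift == k)
      si <- .shift_vec(comp[1, ], k)
      sa <- .shift_vec(comp[2, ], k)
      trials[rows, ] <- trials[rows, , drop = FALSE] +
        rep(si, each = length(rows)) +
        outer(pol[rows], sa)
    }
    art_rows <- which(rbinom(n_tr, 1, spec$artifact_rate) == 1)
    for (r in art_rows) {
      # in-band (150 Hz) damped excursion with unit peak, scaled well beyond
      # 35 uV so the planted artifact survives band-pass filtering
      amp <- (50 + rexp(1, 1 / 20)) * sample(c(-1, 1), 1)
      c0 <- sample(seq_len(n - .ms_to_samples(10, sr)), 1)
      tt <- (0:(.ms_to_samples(10, sr) - 1)) / sr
      burst <- sin(2 * pi * 150 * tt) * exp(-tt / 0.004)
      burst <- burst / max(abs(burst))
      trials[r, c0:(c0 + length(tt) - 1)] <- trials[r, c0:(c0 + length(tt) - 1)] +
        amp * burst
    }
    structure(list(
      trials = trials,
      polarity = ifelse(pol == 1, "condensation", "rarefaction"),
      sample_rate = sr, t0 = ep[1], epoch_window = ep,
      artifact_trials = art_rows
    ), class = "trial_set")
  })
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set> %d trials x %d samples @ %g Hz, epoch %g to %g ms\n",
    nrow(x$trials), ncol(x$trials), x$sample_rate,
    x$epoch_window[1], x$epoch_window[2]
  ))
  invisible(x)
}

#' Draw observed behavioral scores for a cohort
#'
#' Observed scores are the child's true (latent-ability- and age-determined)
#' scores plus measurement noise calibrated so that the correlation between
#' two independent draws equals the spec's `reliability`.
#'
#' @param children Cohort table from [generate_cohort()] (needs the
#'   `*_true` score columns and `age`).
#' @param spec The [cohort_spec()] used to generate the cohort.
#' @param seed RNG seed for the measurement noise.
#' @return A tibble of observed scores, one row per child.
#' @export
draw_scores <- function(children, spec, seed = NULL) {
  tests <- c("phono_awareness", "sentence_recall", "rapid_naming_log",
             "reading_comp")
  rel <- spec$reliability
  .with_seed(seed, {
    out <- lapply(tests, function(tn) {
      tr <- children[[paste0(tn, "_true")]]
      sd_true <- stats::sd(tr)
      sd_err <- if (rel >= 1) 0 else sd_true * sqrt((1 - rel) / rel)
      tr + rnorm(length(tr), 0, sd_err)
    })
    names(out) <- tests
    tibble::as_tibble(out)
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws demographics and a latent preliteracy ability per child, builds each
#' child's response template via [generate_template()], renders each child's
#' trial set via [generate_trials()] (optional), and produces behavioral
#' scores linked to latent ability and age via [draw_scores()]. Deterministic
#' for a fixed `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param render_trials If FALSE, skip trial rendering (templates only);
#'   useful when only the tabular structure is needed.
#' @return A list of class `ffr_cohort` with `children` (tibble: id, age,
#'   sex, nonverbal_iq, latent_ability, group, behavioral scores and their
#'   `_true` counterparts, per-child trial seed), `templates` (list of
#'   [response_template()]), `trial_sets` (list of `trial_set` or NULL), and
#'   `spec`.
#' @export
generate_cohort <- function(spec, render_trials = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  em <- spec$effect_map
  .with_seed(spec$seed, {
    n <- spec$n_children
    ability <- rnorm(n)
    age <- rnorm(n, spec$age_months[1], spec$age_months[2])
    sex <- rbinom(n, 1, spec$sex_ratio)
    iq <- rnorm(n, spec$iq[1], spec$iq[2])
    templates <- lapply(ability, generate_template, spec = spec)
    child_noise <- spec$noise_sd * exp(em$noise_mult * ability)
    child_jitter <- spec$jitter_sd * exp(em$jitter_mult * ability)
    trial_seeds <- sample.int(.Machine$integer.max, n)
    group <- rep(NA_character_, n)
    if (!is.null(spec$ld_fraction)) {
      noisy <- ability + rnorm(n, 0, spec$group_overlap_sd)
      thr <- stats::quantile(noisy, spec$ld_fraction)
      group <- ifelse(noisy <= thr, "LD", "control")
    }
    age_c <- age - spec$age_months[1]
    children <- tibble::tibble(
      id = sprintf("child_%03d", seq_len(n)),
      age = age, sex = sex, nonverbal_iq = iq,
      latent_ability = ability, group = group,
      noise_sd = child_noise, jitter_sd = child_jitter,
      trial_seed = trial_seeds,
      phono_awareness_true = 25 + em$behavior_w * ability +
        em$behavior_age_w * age_c,
      sentence_recall_true = 18 + 0.8 * em$behavior_w * ability +
        0.25 * age_c,
      rapid_naming_log_true = 1.45 - 0.05 * ability - 0.004 * age_c,
      reading_comp_true = 100 + 2.5 * em$behavior_w * ability + 0.5 * age_c
    )
    obs <- draw_scores(children, spec)
    children <- tibble::as_tibble(cbind(children, obs))
    trial_sets <- NULL
    if (render_trials) {
      trial_sets <- lapply(seq_len(n), function(i) {
        generate_trials(templates[[i]], spec, seed = trial_seeds[i],
                        jitter_sd = child_jitter[i], noise_sd = child_noise[i])
      })
    }
    structure(list(children = children, templates = templates,
                   trial_sets = trial_sets, spec = spec),
              class = "ffr_cohort")
  })
}

#' @export
print.ffr_cohort <- function(x, ...) {
  cat(sprintf("<ffr_cohort> %d children, trials %s\n",
              nrow(x$children),
              if (is.null(x$trial_sets)) "not rendered" else "rendered"))
  invisible(x)
}
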