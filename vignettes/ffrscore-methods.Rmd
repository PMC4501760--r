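---
title: "Methods: simulating and scoring consonant-in-noise neural coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring consonant-in-noise neural coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrscore)
```

`ffrscore` turns a single auditory-neurophysiological recording — the
frequency-following response (FFR) to a consonant-vowel syllable in
multi-talker babble — into nine neural predictors and a frozen regression
score for preliteracy. This vignette explains the model behind each stage,
the parameters that matter, what the synthetic data do and do not emulate,
and the numerical choices a careful reader will want spelled out.

## The stimulus and its surrogate masker

The target is a 170 ms [da]: a voiced stop with a 5 ms voice onset time, a
50 ms formant transition (F1 400→720 Hz, F2 1700→1240 Hz, F3 2580→2500 Hz,
linear in Hz), and a 120 ms steady vowel, with F0 = 100 Hz and F4–F6 fixed
at 3300/3750/4900 Hz, sampled at 20 kHz.

The renderer is deliberately not a full Klatt synthesizer. The contract is
spectro-temporal — durations, F0, and formant trajectories — not perceptual
fidelity, so a cascade of six second-order digital resonators (Klatt-style
coefficients, fixed bandwidths 60/90/150/200/250/300 Hz) excited by a
glottal impulse train plus a brief fixed-seed noise burst at onset
reproduces exactly the parameters the analyses depend on. The rendered
vowel is periodic at 10.0 ms, so the autocorrelation-based periodicity
check returns 100 Hz exactly, and the vowel's spectral envelope peaks fall
within ±50 Hz of the steady F1–F3.

The babble surrogate is six independent speech-shaped noise streams (flat
from 100 Hz to a per-talker knee at 500 or 625 Hz, −6 dB/octave above),
each amplitude-modulated at a 4 Hz syllabic rate, summed. Spectral shaping
is circular and the modulation completes an integer number of cycles per
4000 ms loop, so tiling the loop is exactly continuous — the point of the
masker is asynchronous energetic masking, not intelligibility, and real
recorded sentences are out of scope. `mix_at_snr` defines SNR as the ratio
of the target's full-duration RMS to the RMS of the concurrent noise
segment, a convention this package fixes because "+10 SNR" alone does not
determine one.

## What the synthetic cohort emulates

Each simulated child has a latent preliteracy ability `a ~ N(0, 1)` that
drives, through an explicit effect map, both the neural response template
and the behavioral scores. Template parameters are affine in `a` plus
child-level Gaussian noise: peak latencies (default −0.3 ms per SD, i.e.
earlier peaks with higher ability), harmonic amplitudes (+0.02 μV per SD),
the envelope component, and — multiplicatively, on a log scale — the
per-child trial noise SD and latency jitter SD. Behavioral scores are
affine in `a` and age, with measurement noise calibrated so that two
independent draws correlate at the configured test-retest reliability
(default 0.90, matching the disattenuation 0.826/√0.9015 ≈ 0.870 that a
0.826 observed correlation implies). Default demographics follow a
37-child preschool cohort: age 54.41 ± 3.56 months, 21/37 female,
IQ scale score 10 ± 3.

Trials are built as: template, shifted by Gaussian latency jitter (default
SD 0.25 ms, rounded to whole samples), plus an optional 100 Hz component
that flips sign with stimulus polarity (a stimulus-artifact stand-in,
cancelled by polarity addition), plus additive 1/f-weighted noise (default
exponent 1, flat below 10 Hz, SD 0.5 μV), with polarities alternating
strictly. A configurable fraction of trials (default 2%) receives an
injected in-band 150 Hz excursion whose peak exceeds 50 μV, so artifact
trials remain rejectable after band-pass filtering. Transient peaks are
rendered as Gaussian deflections (σ = 0.35 ms, ≈1 ms wide) precisely so
that "the largest strict local maximum" is a well-defined target for the
picker.

Two emulation choices deserve emphasis. First, recordings are simulated at
8 kHz: the analysis band is 70–2000 Hz and the harmonics of interest reach
720 Hz, so a 4 kHz Nyquist is ample, and the 0.125 ms sample period is
well inside the ±0.5 ms recovery tolerance; real acquisition ran at
16.384–20 kHz and nothing in the pipeline depends on that difference.
Second, the online acquisition high-pass (20 dB/decade below 100 Hz,
floored at 0.1 Hz) is applied *at generation time* to both the evoked
components and the noise floor, because the offline "low-frequency boost"
stage exists to undo exactly that hardware filter; without emulating it,
boosting would amplify low-frequency noise that the hardware would have
removed, which is not a situation the offline chain ever faces.

What the generator does **not** emulate: maturational latency differences
across ages, the two acquisition systems' hardware beyond epoch/sweep
metadata, cochlear microphonic morphology, non-Gaussian EEG artifacts
(blinks, movement) beyond threshold-exceeding excursions, or any
quantitative match to published response amplitudes (the μV scales are
plausible, not fitted). Passing recovery tests therefore shows the
*pipeline* is correct and well-conditioned under realistic noise — it does
not validate the biological effect sizes, which are planted.

## The preprocessing chain

Order is fixed and logged: boost → band-pass → epoch/baseline → artifact
rejection → polarity-added averaging.

- **Boost**: an epoch-length FFT gain, 0 dB at and above 100 Hz, rising
  20 dB/decade below, capped at 60 dB (reached at 0.1 Hz). The gain is
  real and even, so the output is real; since only sub-100 Hz bins change,
  the implementation adds the inverse DFT of `(gain − 1)` times those bins
  — algebraically identical to the full FFT multiply, verified against it
  in tests, and an order of magnitude cheaper.
- **Band-pass**: 70–2000 Hz Butterworth of order 2 per pass ("12
  dB/octave roll-off" read as the design order, the standard
  evoked-potential convention), applied forward and backward so net phase
  is zero and the effective roll-off doubles. The row-wise zero-phase pass
  is compiled code using odd-reflection padding and steady-state initial
  conditions; a DC offset therefore vanishes to machine precision, and a
  transient's latency moves by less than 0.1 ms relative to an ideal
  FFT-mask filter.
- **Epoch/baseline**: crop to −40–210 ms (preschool) or −40–190 ms
  (school-age), subtract the per-trial mean of −40–0 ms.
- **Rejection**: a trial is removed iff any sample satisfies |x| > 35 μV
  *strictly* — a tie at exactly 35 μV is retained. The printed "±35 μV"
  does not resolve the boundary; this package fixes and documents it.
- **Averaging**: `final_sweeps` trials (half per polarity, earliest
  retained in presentation order — the deterministic choice where the
  convention is unstated) are averaged as (mean condensation + mean
  rarefaction)/2, cancelling polarity-inverting components to <1%.

## The three metric families

- **Timing**: for each nominal latency (21/31/41/51 ms) the picker takes
  the largest strict local maximum within ±2 ms, clipped to 20–60 ms, ties
  to the earliest. A window with no local maximum yields a *flagged
  missing value*, never an interpolation — this replaces manual editing of
  algorithmic picks with a deterministic, auditable rule. The ±2 ms
  half-width is this package's choice; the naming convention ("a peak near
  21 ms is Peak 21") does not pin down the search bounds.
- **Spectral**: the 20–60 ms segment gets 10 ms raised-cosine ramps at
  *both* edges (one-sided ramping would bias the offset), zero-padding to
  ≥4096 points (≤2 Hz resolution at 8 kHz), and a single-sided amplitude
  spectrum scaled 2|X|/N in μV. "40 Hz bins" is read as centre ±20 Hz,
  amplitude = mean magnitude in the bin; no noise-floor correction is
  applied. H4–H7 are the bins at 400–700 Hz; their mean indexes
  first-formant coding.
- **Stability**: 300 times, the retained trials are split into two
  disjoint, polarity-balanced halves (a random partition, not two
  independent draws — "each sub-average comprised 50% of the trials"
  implies complementary halves); each half is polarity-added and averaged;
  the two sub-averages are correlated over 20–60 ms. The mean r is
  Fisher-transformed with clipping at |r| = 1 − 10⁻¹², flagged when
  clipping occurs (atanh diverges at ±1). An odd per-polarity count drops
  one trial, logged.

## The scoring model and its transfer

Step 1 regresses the outcome on sex (male = 0, female = 1), age in months,
and non-verbal IQ; Step 2 adds the nine neural predictors. Reported:
R² per block, ΔR², F-change with (k₂, n − k₁ − k₂ − 1) degrees of freedom,
two-tailed p-values throughout, standardized βs from z-scored columns of
the fitting sample, and per-predictor tolerances (1 − R² of each predictor
on the others). Missing values are deleted listwise for fitting; in
transfer, a child missing any predictor gets a flagged `NA` score —
imputation would smuggle assumptions into a frozen model. Transfer itself
uses raw-scale coefficients only and sets `refit_flag = FALSE`; nothing in
the prediction path can re-estimate anything. Preliminary single-family
models (timing-only, spectral-only, stability-only second blocks) are the
same function on column subsets, not separate code.

Disattenuation divides r by √reliability (outcome side only, capped at 1),
because the correction targets the behavioral test's unreliability; the
reliability itself is a configuration value, default 0.90.

Cross-validation refits on a random `n_train` (default 20 of 37) and
transfers frozen to the rest. A note on calibration: with 12 predictors on
20 training children the holdout correlation estimates the *trained
model's population correlation* — which shrinkage places well below the
generative √R² — so the package's tests compare the holdout mean to that
population value measured by brute force on a large fresh cohort, not to
the inflated in-sample r.

## Classification

The discriminant stage is a single-variable linear discriminant
(MASS::lda) with observed class frequencies as priors (the conventional
default; equal priors are one switch away, and with one predictor and
equal priors the rule reduces exactly to the pooled-means midpoint
threshold). Wilks λ = SS_within/SS_total, χ² = −(n − 1 − (p + g)/2)·ln λ
on p(g − 1) df, plus the one-way F on group means; accuracy is
resubstitution, matching how such analyses are conventionally reported.
The ROC sweeps all observed thresholds with the *control* group as the
positive class — the score's clinical use is "clearing" children as
unlikely to be reading impaired — AUC equals the scaled Mann–Whitney U
(exhaustive pairwise comparison is the test oracle), the 95% CI uses the
Hanley–McNeil standard error, and the AUC = 0.5 test is a two-sided z on
that SE. A single-valued score degenerates to AUC 0.5 with a flag.

## Numerical choices and problem sizes

- Fisher clipping ε = 10⁻¹²; strict-inequality rejection boundary;
  earliest-trial sweep selection; ties in peak picking to the earliest
  sample — every tie-break is deterministic.
- Colored noise is synthesized directly in the frequency domain (a
  non-Hermitian complex Gaussian spectrum inverts to two independent real
  streams per FFT), and the boost touches only the bins it changes; both
  are exact, not approximations, and keep a 4200-sweep child under ~4 s.
- The test suite's recovery study uses 50 children × 4200 sweeps at the
  boundary conditions (jitter SD 0.3 ms, per-trial SNR −10 dB, 4000
  retained sweeps); stability monotonicity uses a 5-point noise grid × 10
  seeds at 200 trials; regression recovery uses n = 2000; the permutation
  null uses 1000 label shuffles at n = 55. These sizes are the package's
  chosen balance of statistical resolution against a test suite that runs
  in minutes.
- Harmonic-amplitude recovery is asserted as the pooled Spearman rank
  correlation over all child × harmonic pairs (≥0.9). Per-harmonic
  rank recovery across children is weaker at the upper harmonics (≈0.82 at
  600–700 Hz): the ~1 ms Gaussian transients are broadband, and their
  leakage into the upper bins is comparable to the small planted
  between-child spread there. That interaction is a property of any
  response that superimposes transients on tonal components, not a bug;
  the vignette states it so nobody mistakes the pooled statistic for a
  per-harmonic guarantee.

## Known limitations

The babble and syllable are surrogates, adequate for pipeline contracts
but not perceptually validated. Response morphology beyond peak/harmonic
parameters is invented, so absolute μV values should not be compared to
published figures. The acquisition emulation covers filters and sweep
counts, not amplifier nonlinearities or electrode impedance drift. And the
regression machinery is deliberately plain OLS — no mixed effects, no
shrinkage — because the scientific claim under test is the frozen-transfer
design, not estimator sophistication.
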