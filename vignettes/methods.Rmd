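---
title: "Models, parameters and numerical choices in nirsbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and numerical choices in nirsbp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsbp)
```

## Scope and model

`nirsbp` analyses a two-manipulation, event-related protocol: brief reversing
visual stimuli (1500 or 3000 ms) evoke cortical haemodynamic responses, while
on half the trials a rapid arm raise produces a transient systemic
blood-pressure increase that is independent of the visual stimulation.
Two optical channel depths are modelled: a *deep* channel (4 cm
source–detector separation, sampling visual cortex) and a *shallow* channel
(1 cm, sampling only extracranial tissue). The scientific question the
pipeline serves is whether, and through which tissue compartment,
the pressure transient contaminates the optical responses.

### Chromophore unmixing

Optical-density changes at two wavelengths are converted to ΔO₂Hb/ΔHHb (µM)
by solving, per sample, the 2×2 linear system of the modified Beer–Lambert
law, with path length *d*·DPF(λ, age). Because the system is linear and tiny,
we solve it with a precomputed matrix inverse; correctness is pinned by an
exact round-trip identity (forward then inverse ≤ 1e−9 µM over 10,000 random
samples) and an independent Cramer's-rule oracle (≤ 1e−12) in the test suite.

Two coefficient tables ship with the package and are deliberately
*user-replaceable CSV files*, each carrying its provenance in the header:

* `extinction_coefficients.csv` — decadic molar extinction coefficients for
  O₂Hb and HHb, 690–900 nm, linearly interpolated to the requested
  wavelength. Published compilations differ by a few percent; the package
  treats the table as data, not truth, and defines correctness by the
  algebraic contracts above.
* `dpf_duncan.csv` — coefficients of the age dependence
  DPF(age) = a + b·age^c. The published cranial values exist at
  690/744/807/832 nm only; rows for the device wavelengths 764 and 859 nm are
  derived by linear interpolation/extrapolation of (a, b, c) across
  wavelength and flagged `derived` in the file. `dpf()` refuses wavelengths
  without a table row and names the available ones, rather than silently
  interpolating a power-law exponent.

The ±20 nm source bandwidth is ignored (no spectral integration), the normal
convention for continuous-wave instruments.

## Analysis parameters

Every default in `analysis_params()` is the protocol value:

| parameter | default | unit | role |
|---|---|---|---|
| `nirs_lowpass_hz` | 1 | Hz | NIRS anti-cardiac/noise low-pass |
| `bp_lowpass_hz` | 10 | Hz | pressure waveform conditioning |
| `detrend_degree` | 5 | — | whole-session polynomial drift removal |
| `nirs_window_s` | [−0.5, 12) | s | NIRS epoch relative to onset |
| `bp_window_s` | [−0.5, 10) | s | pressure epoch |
| `baseline_s` | [−0.5, 0) | s | pre-stimulus baseline |
| `reject_k` | 3 | SD | outlier-epoch criterion |
| `map_method` | waveform_mean | — | per-beat MAP definition |
| `family_alpha` | 0.05 | — | family-wise error over 3 contrasts |

Design choices where the protocol left the implementation open:

* **Filter realization.** Only cutoffs are specified; we use a 4th-order
  Butterworth applied forward–backward. Zero phase is essential because
  response *latency* is a primary outcome; a causal filter would bias it by
  the group delay. The effective magnitude response is the squared
  single-pass response (≈ 2.6e−6 at 5 Hz for the 1 Hz NIRS filter).
* **Detrend domain.** "The baseline" is read as the whole-session slow trend:
  one least-squares polynomial per channel per input file, time rescaled to
  [−1, 1] for conditioning. Session-wise (rather than pooled) detrending is
  also the default for multi-file inputs.
* **Outlier statistic.** The ±3 SD criterion does not say *of what*. We use
  each epoch's peak absolute deviation from baseline, pooled within condition
  cell, with mean/SD including the candidate, in a single deterministic pass
  (no re-iteration on survivors). The per-epoch statistic and decision are
  logged (`tables/rejections.csv`) so users can audit every exclusion.
* **MAP definition.** `waveform_mean` integrates the clamped waveform from
  one diastolic trough to the next — the physically meaningful beat average —
  with `onethird` (DBP + PP/3) as a waveform-free fallback.
* **Test family.** The planned comparisons use unpaired pooled-variance
  t-tests, matching the protocol's description, although the design is
  within-session; a `paired` option is exposed. The critical alpha is
  `family_alpha/3`, displayed rounded to 3 decimals (0.017) but applied
  unrounded.
* **Metric polarity.** O₂Hb responses are measured as maxima. HHb polarity
  follows the compartment physiology: minima in the deep channel (flow
  increase washes out HHb) but maxima in the shallow channel (extracranial
  volume increase raises both chromophores).
* **Regression unit.** Whether coupling correlations are computed over time
  points or trials is ambiguous in the field; the default regresses
  condition-averaged time-courses point-wise over the shared [−0.5, 10) s
  window (n = 525 at 50 Hz), which is what the trace figures display. The
  per-trial-amplitude route is available by regressing the rows of the
  per-trial metrics tables directly.

## The synthetic generator

`simulate_session()` states a world; its defaults are the emulated study's
published group means, fixed once:

* Design: 15 trials per 2×2 cell (60 total), randomized order, ITI drawn
  from N(19.2, 2.9²) s truncated below at μ − 2σ = 13.4 s. The truncation
  preserves the printed moments to ≈ 0.8% (truncated mean 19.36 s) while
  guaranteeing that [−0.5, 12) s epochs can never overlap; configurations
  whose floor would drop below 13 s are rejected at validation.
* Pressure: one beat per cardiac period at a constant 70 bpm — a raised-cosine
  systolic upstroke (80 ms) then an exponential decay rescaled to land exactly
  on the diastolic level at the period's end, so the template's extrema are
  unambiguous for the peak-picker contract. Movement trials add gamma-shaped
  transients to the systolic/diastolic envelopes: +7.8 mmHg peaking 5.8 s
  after onset (systolic), +5.6 mmHg at 5.1 s (diastolic).
* Haemodynamics: per-trial single-gamma responses in the deep channel
  (O₂Hb +0.26 µM peaking 8.6 s for 1500 ms stimuli, +0.38 µM at 10.4 s for
  3000 ms; HHb −0.09/−0.11 µM at 7.4/8.8 s), none in the shallow channel.
* Coupling: the MAP-deviation envelope times a gain —
  shallow O₂Hb 0.066 µM/mmHg and HHb +0.0136 µM/mmHg (the published 0.08 µM
  mean response divided by the 5.9 mmHg MAP transient; the shallow HHb gain
  is only constrained to be "small and positive", so its magnitude is an
  explicit free parameter), deep O₂Hb 0.063 and HHb −0.012 µM/mmHg.
* Nuisance: degree-3 slow drift (≤ 0.5 µM), cardiac pulsation (0.1 µM O₂Hb,
  a quarter of that in HHb), white noise of SD 0.05 µM per chromophore —
  magnitudes a working CW-NIRS lab would call a clean seated recording.
  The ground-truth chromophore traces then pass through the forward
  Beer–Lambert model to emit raw two-wavelength optical densities.

### The transient's gamma shape: an error budget

The transient shape parameter k (gamma with unit-peak parameterisation,
peak fixed at 5.8 s) is a free choice bounded by two contracts pulling in
opposite directions:

* *Tail bleed*: a slow gamma still carries a large fraction of its peak at
  the 13 s minimum ITI, contaminating the next trial's baseline.
* *Beat-sampling smoothing*: the pipeline reads the transient through beats
  ~0.86 s apart and linear interpolation, which convolves it with a
  triangular kernel; the peak loss is ≈ (k−1)·Δ²/(12·t_p²) ≈ 0.18%·(k−1)
  at 70 bpm.

k = 12 (the tail-optimal choice) loses ~2% to smoothing alone and fails the
2% amplitude-recovery contract; k = 8 balances the budget (smoothing ≈ 1.3%,
mean tail contamination ≈ 0.1% under the truncated-normal ITIs) and matches
a return-to-baseline within ~10 s. The HRF uses k = 10, where no
beat-sampling is involved and only tail bleed matters.

### What a green test does and does not establish

The generator emulates: jittered event-related timing, pulsatile pressure
with arm-raise transients, condition-dependent gamma HRFs, pressure-coupled
channels of both depths, drift, cardiac artifact and white noise. It does
*not* emulate: motion artifacts, heart-rate variability or respiratory
modulation, device calibration gaps, height-reference errors, the arm-lowering
act (outside the analysis epoch), trial-to-trial HRF variability, or
between-participant variance — the pipeline's group-level helpers are
exercised only on within-session trial samples. Parameter-recovery tests
therefore establish the correctness of the analysis chain, not the realism
of any one noise model.

## Numerical choices and degenerate inputs

* Filtering uses steady-state initial conditions plus odd-reflection padding
  (≥ 3 filter time constants), so constants pass exactly and narrowband edge
  transients die inside the padding. A discontinuity between a trace's start
  and end values still produces a localized edge artifact — intrinsic to
  reflection padding — which is why stopband tests use boundary-continuous
  tones.
* Epoching uses half-open windows on the source grid (onset sample included
  at t = 0; 625 samples for [−0.5, 12) at 50 Hz). Onsets whose window leaves
  the recording are dropped with a warning and logged, not fatal.
* Zero-variance t-tests report t = ±∞ with p = 0 (or t = 0, p = 1 when the
  means also coincide) plus a `degenerate` flag and warning, so null
  simulations sweep cleanly. All-flat epochs yield amplitude 0 with latency
  NA; planned comparisons propagate undefined measures as NA rows flagged
  non-significant rather than aborting the family.
* Ties in the extremum search break to the earliest time; `auto` polarity
  picks the larger absolute extremum.
* Determinism: one integer seed drives schedule and noise (per-mode offsets
  +1/+2 keep deep and shallow streams independently reproducible); all CSV
  output is written at 9 significant digits and provenance carries no
  timestamps, so identical seeds give byte-identical result directories.

## Known limitations

* Single-channel-per-depth simulation; the analysis accepts multi-channel
  recordings but the generator does not emulate optode montages.
* No SNIRF/HDF5 ingestion; plain-CSV schemas only.
* The statistical helpers implement the protocol's tests (one-sample,
  pooled two-sample, OLS regression); mixed-effects or GLM-based confound
  regression is out of scope.
* Extinction coefficients are an approximate compilation; users reproducing
  absolute concentrations against other software should substitute their
  laboratory's table and expect few-percent scale differences.
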