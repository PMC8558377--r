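---
title: "Methods: detection and thermal analysis of sharp-wave ripples and interictal discharges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection and thermal analysis of sharp-wave ripples and interictal discharges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`thermoripple` implements the offline analysis of hippocampal local field
potentials (LFP) recorded while core body temperature is slowly raised — the
protocol used to study thermally evoked seizures in Dravet-syndrome (DS)
mouse models against wild-type (WT) littermates. The pipeline has four
stages:

1. **Preprocessing.** Channels are brought to 2048 Hz (anti-alias low-pass
   at 1024 Hz before decimation), band-passed with zero-phase FIR filters
   (ripple 100–260 Hz, sharp wave 10–20 Hz, EMG 200–700 Hz), and converted
   to instantaneous power via the squared magnitude of the Hilbert analytic
   signal. Every power or amplitude trace is z-scored,
   `z(t) = (f(t) - mean) / sd`, with mean and SD taken from a reference
   epoch of NREM-like quiet immobility. That anchoring is the core
   normalization assumption: thresholds are expressed in baseline SD units
   so that detection is invariant to electrode gain and impedance.

2. **SPW-R detection.** Candidate epochs are maximal regions where smoothed
   ripple-band power exceeds 3 SD, extended to the surrounding 0.5 SD
   envelope so the first and last cycles are not truncated, merged across
   gaps under 20 ms, and discarded if they touch active-exploration
   segments. Within each epoch, troughs of the ripple-band trace become
   cycles only if the inter-trough interval lies in 4–10 ms; the internal
   ripple frequency is the reciprocal of the mean interval over the five
   middle cycles (three if the event has fewer than six cycles). Event
   start and end are the first and last accepted troughs.

3. **Discharge detection.** Interictal spikes are samples where broadband
   LFP amplitude exceeds 1 SD while the first derivative exceeds 5 SD,
   collapsed to one event per 100 ms and aligned to the largest-|z|
   extremum. Myoclonic events are separated from interictal spikes by the
   EMG power ratio of the 100 ms windows after vs before the spike
   (strictly greater than 2 means myoclonus). A generalized tonic-clonic
   seizure (GTC) is an annotated onset or, absent an annotation, the first
   period of at least 5 s with both broadband LFP power and EMG power above
   5 SD.

4. **Thermal aggregation.** Event rates are events divided by dwell time in
   0.5 °C bins; ripple frequency is averaged in 0.25 °C bins; spectral
   frequency per 1 °C bin is the center of a Gaussian fitted to the Welch
   spectrum of concatenated immobility data. All aggregation is
   per-subject first, then across subjects (grand average ± SEM); events
   are never pooled across animals. Temperature-binned statistics use only
   the pre-ictal span (before GTC onset minus a 2 s guard) during
   immobility.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `ripple_power_threshold` | 3 | z | candidate SPW-R threshold |
| `envelope_threshold` | 0.5 | z | epoch boundary extension |
| `cycle_period_min/max` | 4 / 10 | ms | accepted inter-trough interval |
| `trough_depth_frac` | 0.3 | — | minimum trough depth vs the event's deepest |
| `spike_amp_threshold` | 1 | z | discharge amplitude gate |
| `spike_deriv_threshold` | 5 | z | discharge slope gate |
| `morphology_min_amp` | 8 | z | artifact-review morphology floor |
| `emg_state_threshold` | 1.5 | z | active-exploration boundary (1–2 sensible) |
| `emg_window` | 100 | ms | myoclonus pre/post EMG windows |
| `emg_ratio_threshold` | 2 | — | strict post/pre myoclonus ratio |
| `alignment_temperature` | 38.5 | °C | anchor for seizure-free sessions |
| `spw_split_temperature` | 38 | °C | SPW amplitude paired comparison |
| `power_smooth` | 20 | ms | ripple-power smoothing before z-scoring |

The baseline epoch is auto-selected as the 60 s window minimizing mean EMG
power, subject to a theta-dominance veto (6–10 Hz power must not exceed
1–4 Hz power), ties resolved to the earliest window; a manual epoch in the
run configuration overrides it. Because quiet sleep-like epochs contain
SPW-R, the baseline SD of ripple power is deliberately ripple-inflated —
that is what makes a 3 SD threshold selective rather than a fixed multiple
of the noise floor.

## Design choices where the design was open

- **Derivative trace.** The discharge slope criterion is computed on a
  70 Hz low-passed copy of the LFP. On the raw broadband trace the first
  derivative is dominated by ripple-band oscillation and wideband noise,
  and ordinary SPW-R would satisfy a 5 SD derivative threshold; the steep
  deflection that defines an epileptiform discharge lives below the ripple
  band, and low-passing isolates it.
- **Separate baselines per quantity.** Amplitude, derivative, and each
  band's power are z-scored against their own statistics from the same
  epoch; reusing amplitude statistics for the derivative would make the
  slope threshold depend on the noise spectrum.
- **Artifact review stand-in.** Manual review is replaced by three
  deterministic rules: events during active exploration; coincident
  multi-channel deflections with sustained (≥ 250 ms) EMG elevation that
  begins more than 150 ms before the spike; and a morphology floor (an
  aligned extremum below 8 SD is a background or sharp-wave deflection
  whose derivative grazed the threshold — even a stepped sharp wave with a
  superimposed ripple trough stays near 7.5 SD, while genuine discharges
  exceed 13 SD). A CSV of manual verdicts overrides all rules.
- **Ripple filter length.** Band filters use a Hanning-window FIR of
  `3 fs / low-edge` taps applied forward–backward (zero net phase). For the
  ripple band specifically the kernel is doubled (123 taps at 2048 Hz): the
  shorter kernel's transition slope across 100–260 Hz tilts the spectrum of
  slow (~135 Hz) ripples and biases their inter-trough frequency upward by
  about 3 Hz.
- **Trough interpolation and guards.** Extrema are located by sign change
  of the discrete derivative (ties to the earlier sample) and refined by
  quadratic interpolation; interval bounds carry a 10 µs numerical guard so
  an interval of exactly 10 ms is accepted. Samples within one filter
  length of the record edges are excluded from all detection.
- **Ripples coincident with discharges.** An epileptiform transient also
  carries ripple-band power, so SPW-R detections within 100 ms of a
  non-artifact discharge (and within the GTC span ± 2 s) are excluded
  rather than double-counted.
- **EMG ratio re-centering.** z-scored power can be zero or negative, so
  both window means are shifted by +1 baseline SD and floored at 0.01
  before the ratio; quiet EMG then gives a ratio near 1, and the
  classification is invariant to global EMG gain.
- **Bin convention.** Temperature bins are `[center − w/2, center + w/2)`
  with centers at multiples of the width anchored at 36.0 °C.
- **Sigmoid and Gaussian fits.** Rate trends use a 4-parameter logistic;
  spectral peaks use a Gaussian plus constant offset on the 100–260 Hz
  slice, with "no peak" declared when the fitted amplitude is below twice
  the residual SD. Non-convergent fits are flagged, never fabricated. No
  multiple-testing correction is applied (two-sided α = 0.05 throughout).

## The synthetic-session generator

The generator exists so every stage can be validated against a known
ground truth. One session seed drives three derived streams (temperature
profile, event schedule, waveform rendering), so equal seeds give
bit-identical sessions. It emulates:

- a baseline plateau near 36 °C, a 0.5 °C/min ramp (free parameter; the
  protocol is only described as slow) to the seizure temperature (DS) or
  the 40 °C cap (WT), then exponential cooling;
- SPW-R as Gaussian-windowed 12 Hz sharp waves with superimposed
  Gaussian-enveloped ripples whose frequency follows
  `f(T) = f36 + 8 (T − 36)` Hz plus 3 Hz per-event jitter, clipped to
  100–250 Hz, with `f36` = 175 Hz (WT) or 135 Hz (DS);
- an inhomogeneous Poisson SPW-R intensity — monotone increasing in WT,
  peaking at 37.5 °C in DS — with 0–3 burst followers per seed event at
  80–200 ms gaps;
- DS discharge classes appearing above their onset temperatures
  (interictal spikes 37.8 °C, myoclonus 38.8 °C, GTC at the first crossing
  of 38.9 °C), a 1.6× sharp-wave amplitude step at 38 °C, 1 s post-spike
  SPW-R suppression (×0.15) and deep post-ictal suppression;
- myoclonic EMG bursts starting at the spike peak, a 15 s polyspike GTC
  with sustained EMG, an exploration epoch with elevated EMG, theta and
  movement transients, and 1/f^1.5 background LFP with white and 20–60 Hz
  components (the mid-band component gives the sub-ripple derivative trace
  a realistic noise floor).

What it does **not** emulate: spike waveform diversity, electrode drift,
chewing/grooming artifact families, true sleep architecture (REM is absent
by design, matching the recordings the analysis targets), volume-conduction
correlations between channels, and any biophysical network mechanism.
Passing recovery tests on these sessions therefore shows the pipeline is
correct *given its signal model*; it does not certify performance on every
real-world artifact regime, which is exactly why the manual-override file
exists.

## Numerical behavior and known limitations

- **Cycle-rule truncation at the band edges.** The 4–10 ms acceptance rule
  makes frequency estimates near 100 Hz and 250 Hz biased inward: at
  250 Hz the true interval sits exactly on the 4 ms bound, so noise jitter
  rejects about half the cycles and the surviving ones are long. This is a
  property of the rule, not of the estimator (it persists under longer
  filters and upsampled extrema detection). Estimates are unbiased within
  about 1 Hz over 135–225 Hz, the range the presets generate.
- The first-event onset-temperature statistic is fragile to a single false
  positive; the morphology floor exists mainly to protect it.
- `select_baseline_epoch` assumes at least one quiet minute; uniformly
  active recordings produce an error advising a manual epoch.
- Welch spectra concatenate discontiguous immobility segments; segment
  boundaries add broadband leakage that the Gaussian offset term absorbs.

## Problem sizes used in the shipped studies

The recovery studies run at the sizes the analyses need, chosen to keep a
full check affordable on a laptop: frequency recovery uses one 700 s
constant-36 °C session per genotype (~300 injected SPW-R each, comfortably
above the 200 the study design asks for); onset/rate recovery uses a
cohort of six seeded DS induction sessions (~11 minutes of recording
each); unit tests use seconds-long constructed signals.
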