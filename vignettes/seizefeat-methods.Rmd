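---
title: "Classifier-free seizure detection: the feature-signal method"
author: "seizefeat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifier-free seizure detection: the feature-signal method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizefeat)
```

## The idea

Most automated seizure detectors are classifiers: they extract spectral or
nonlinear features from the EEG and train a model per patient. That
training requirement makes them hard to use on a new patient, in an ICU,
or anywhere labelled data do not exist. The method implemented here takes
the opposite route: it treats the seizure as the *carrier* in a noisy
transmission channel and tunes a fixed filter chain to its band. The whole
multichannel record collapses into one normalized "feature signal" whose
baseline breaks visibly at a seizure; detection is then a handful of
amplitude, width and power rules on that single trace — no classifier, no
training, identical parameters for every patient.

The pipeline, per one-hour record:

1. **Per-channel denoising** (`preprocessRecording()`):
   power-line notch → 35 Hz FIR low-pass → recursive DC-removal notch.
2. **Collapse** (`buildFeatureSignal()`): arithmetic average of all EEG
   channels → full-wave rectification → seizure-band feature filter
   (0.1–4.1 Hz) → 150-sample moving RMS → division by the record maximum.
3. **Detection** (`detectSeizures()`): onset peaks with height ≥
   `ampUpper`, half-prominence width within 0.4–1.8 s and in-band power ≥
   `powerThreshold` seed epochs, which grow to the surrounding region above
   `ampLower` and merge across gaps shorter than `minEpochSamples`.
4. **Localization** (`localizeEpochs()`): the same per-channel processing
   restricted to the detected epochs; channels whose amplitude excursion
   exceeds the median over channels are reported as the origin, and their
   10–20 electrode prefixes vote a cortical lobe.
5. **Evaluation** (`matchEvents()`, `metricsReport()`,
   `aggregateMetrics()`): record-unit confusion counts under an
   any-overlap rule and the six standard percent metrics plus FP/h.

## Parameters and their meaning

| parameter | default | unit | role |
|---|---|---|---|
| `lpCutoff`, `lpOrder` | 35, 50 | Hz, – | FIR low-pass removing EMG and high-frequency noise |
| `powerlineFreq` | 60 | Hz | notch fundamental (50 for European recordings); harmonics below Nyquist are notched too |
| `notchQ` | 60 | – | per-section notch quality factor |
| `dcLambda` | 0.9991 | – | pole radius of H(z) = (1 − z⁻¹)/(1 − λz⁻¹) |
| `bandLo`, `bandHi` | 0.1, 4.1 | Hz | seizure band of the feature filter |
| `ffOrder` | 30 | – | feature-filter FIR order |
| `rmsWindow` | 150 | samples | moving-RMS window (~0.6 s at 256 Hz) |
| `ampLower` | 0.075 | fraction of 1 | epoch-extent threshold and minimum peak prominence (sensible range 0.05–0.1) |
| `ampUpper` | 0.9 | fraction of 1 | onset-peak height threshold (sensible range 0.8–1) |
| `widthMinS`, `widthMaxS` | 0.4, 1.8 | s | admissible onset-discontinuity width |
| `powerThreshold` | 200 | µV²·s | in-band power floor excluding broadband artefacts (sensible range 180–220) |
| `minEpochSamples` | 256 | samples | minimum epoch length and merge gap (1 s at 256 Hz) |

Normalization is per record, so the amplitude thresholds are fractions of
one regardless of montage gain; the power test deliberately uses the
*unnormalized* filtered average, which is what lets it reject records
whose largest envelope excursion is an artefact rather than a seizure.

## Numerical choices

**Zero-phase filtering.** Every stage runs forward–backward
(`zeroPhaseFilter()`), so the magnitude response is squared and the phase
is exactly zero — epoch timing is unbiased. Edge transients are suppressed
by odd-reflection padding of 3× the effective filter length; for the
recursive DC notch the effective length is the settling time of the slow
pole (≈15,000 samples at λ = 0.9991), capped by the record length. A
causal single-pass mode (`zeroPhase = FALSE`) exists for real-time style
processing.

**The DC notch.** H(z) = (1 − z⁻¹)/(1 − λz⁻¹) has exactly zero gain at DC;
at fs = 256 Hz and λ = 0.9991 its −3 dB point is ≈0.037 Hz. Constant
offsets are annihilated; what remains in a finite window is band noise
whose *sample mean* is stochastic and does not vanish — a 2-minute noise
window typically retains a sample mean of a few percent of its RMS, and
even an hour retains ~10⁻³. The meaningful invariant (tested) is that an
added offset contributes less than 10⁻⁶ of itself to the output.

**Power-line notch.** The notch is a cascade of constrained biquads at the
fundamental and every harmonic below Nyquist. Q defaults to 60: under
forward–backward application a Q of 30 would droop the passband by ~1.8%
five hertz from the notch, while Q = 60 keeps it within ~0.5%, preserving
the contract that the notch is surgical.

**Feature filter.** A 30th-order FIR at 256 Hz cannot realize a 0.1 Hz
high-pass edge (its transition band is tens of hertz wide), and the DC
notch already owns the low edge, so by default only the 4.1 Hz low-pass
component is applied; `applyHighpass = TRUE` adds the literal high-pass
stage for fidelity experiments. Rectification precedes the feature filter
(switchable via `rectifyFirst`): folding the ictal oscillation into its
amplitude trace is what makes a 0.6 s RMS window able to follow it.

**Linearity shortcut.** All preprocessing stages are LTI with identical
coefficients on every channel, so the average of the preprocessed channels
equals the preprocessed average. `buildFeatureSignal()` therefore averages
first and filters once — one channel's cost instead of 23 — with
bit-for-bit determinism. This is also the method's data-reduction claim:
the stored feature signal is 1/n_channels the size of the input.

**Peak rules.** Local maxima are found with plateau ties resolved to the
leftmost sample; prominence is the standard topographic definition; width
is the contiguous run of samples above height − prominence/2 (peaks
clipped by the record edge are measured on the available support). We read
`ampUpper` as a lower bound on onset-peak height ("the discontinuity must
reach the top decile of the record") rather than a saturation-rejection
cap; the alternative reading can be emulated by lowering `ampUpper` and
filtering on the reported `peakValue`.

**Localization.** Scores are computed segment-locally (the epoch ± 5 s of
context, per-channel demeaned) rather than on the whole record; this makes
per-epoch scoring cheap and exactly invariant to per-channel offsets. The
literal median rule selects up to half the channels; the `margin`
multiplier (default 1.0 = literal rule; ~1.5 recommended on real data)
lets users tighten the selection, and the full score table is always
returned so re-thresholding needs no recomputation. Amplitude excursions
are measured on the rectified, feature-filtered channel — the same
processing the feature signal uses — because the rule's job is to find the
channels that drove the average.

**Manual mode.** `picksToEpochs()` accepts onset/offset second pairs (from
any point-marking UI or a two-column file) and applies the same
minimum-duration, merge and minimum-length rules; pairs closer than
`widthMinS` are flagged as not-a-seizure and dropped.

## What the synthetic generator emulates

`simulateRecording()` produces the signal classes the detector must
separate, each with a realistic scalp-EEG scale:

* pink-noise background, σ = 30 µV, with occasional 1 s, 10 Hz alpha
  bursts (20 µV) on small channel subsets;
* slow drift (< 0.05 Hz, 30 µV), per-channel DC offsets up to ±200 µV and
  a common 60 Hz interference (10 µV) — everything the preprocessing
  cascade exists to remove;
* jaw/EMG bursts: 0.1–0.3 s of 20–35 Hz activity at 80 µV, independent
  across channels — large in amplitude but nearly bandless after the
  feature filter, which is exactly the artefact class the power threshold
  rejects;
* seizures: 30–120 s of ramped rhythmic 1–4 Hz activity with a
  second-harmonic spike component at 7× the background σ (~210 µV) on a
  6-channel subset, opening with a 0.5 s high-amplitude onset complex at a
  fixed 3 Hz — the "baseline discontinuity" the detector keys on. The
  generator asserts, per injected seizure, that the ictal in-band
  (0.1–4.1 Hz) RMS exceeds 3× the adjacent seizure-free background on
  every injected channel.

Corpus records (`simulateCorpusRecord()`, `makeTestSuite()`) each get an
RNG stream keyed by (seed, index); every fifth record is artefact-only so
the false-alarm rate is measurable. The validation suite uses 50 records
of 10 minutes each — a deliberate compression of the method's one-hour
operating unit that keeps the full pipeline (including localization of
every epoch) affordable while preserving per-record normalization, the
artefact mix and multi-seizure layouts.

What the generator does *not* emulate: real ictal morphology evolution
(frequency gliding, post-ictal suppression), age-dependent rhythms
(infant EEG differs fundamentally and is the method's known weak point on
real data), electrode pops, chewing sequences, or montage changes
mid-record. Passing the synthetic recovery suite therefore shows the
rules are implemented coherently and separate the modelled signal classes
— it does not certify clinical performance, which on the public benchmark
corpus requires the external download scripted in
`inst/scripts/chbmit_validate.R`.

## Degenerate inputs and tie-breaks

An all-zero record yields a zero envelope with `normFactor` 0 (no division
error) and no detections. Plateau peaks take the leftmost sample. Epochs
are half-open in seconds ((start−1)/fs, end/fs) and 1-based closed in
samples, converted by floor/ceil so annotation round-trips never lose
coverage. Overlapping annotations merge on load; merging never reduces
covered time. Metrics with zero denominators return `NA` — deliberately
neither 0 nor 100 — and aggregation skips them.

## Known limitations

* The onset-discontinuity operationalization (height ≥ `ampUpper`, width
  0.4–1.8 s) requires the seizure to produce a sharp envelope transient;
  slowly-ramping seizures with no onset complex are missed by the
  automated rule (manual mode exists precisely for them).
* Per-record normalization means a record's largest artefact reaches 1.0
  by construction in seizure-free records; the unnormalized power test is
  the only guard there, so `powerThreshold` is the parameter to retune
  first on a new montage or amplifier gain.
* Record-unit true negatives follow the benchmark's table convention; an
  hour-segment unit changes specificity and is available in the evaluator
  but is not the default.
* EDF support covers continuous 16-bit EDF/EDF+ with a single sampling
  rate across EEG channels; discontinuous (EDF+D) and BDF files are out
  of scope.
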