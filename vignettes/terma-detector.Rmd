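---
title: "Two event-related moving averages: the method behind terma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two event-related moving averages: the method behind terma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terma)
```

## The detection problem

A single-lead ECG records the heart's electrical activity as a sequence of
P-QRS-T complexes. The QRS complex — the sharp deflection produced by
ventricular depolarization — is the fiducial event for almost everything
downstream: heart-rate estimation, arrhythmia analysis, heart-rate
variability. Detecting its apex (the R peak) reliably is complicated by
baseline wander (respiration, electrode motion, < 1 Hz), powerline
interference (60 Hz and harmonics), broadband muscle noise, and by the
beats themselves: inverted, widened, or biphasic QRS morphologies, tall T
waves, low-amplitude complexes.

`terma` implements a deliberately simple, knowledge-based detector built
from two moving averages, together with the machinery around it: a
brute-force parameter optimizer, beat-matching evaluation, a Pan-Tompkins
comparator, and a synthetic ECG generator that makes the whole stack
testable without any external recordings.

## The detector

For a record $s[n]$ sampled at $f_s$ Hz:

1. **Band-pass filter.** A third-order Butterworth filter with passband
   $f_1$–$f_2$ Hz (default 8–20 Hz) is applied forward and backward
   (zero phase), giving $x[n]$. The low edge removes baseline wander and
   suppresses P and T waves; the high edge removes muscle and mains noise
   while retaining most QRS energy.
2. **Squaring.** $y[n] = x[n]^2$: nonnegative, emphasizes large
   deflections.
3. **Two event-related moving averages.** A QRS-scale average with window
   $W_1$ (default 97 ms; 35 samples at 360 Hz) smooths $y$ over one
   complex; a beat-scale average with window $W_2$ (default 611 ms;
   220 samples at 360 Hz) tracks the per-beat energy level.
4. **Dynamic threshold.** $\mathrm{THR} = \mathrm{MA}_{beat}[n] + \alpha$
   with $\alpha = \beta\,\bar z$, where $\bar z$ is the mean of $y$ over
   the record and $\beta$ (default 0.08) the offset fraction. Maximal runs
   with $\mathrm{MA}_{qrs}[n] > \mathrm{THR}[n]$ are *blocks of interest*.
5. **Width rejection.** Blocks narrower than $W_1$ samples are rejected
   (P/T waves, noise); the comparison is greater-than-or-equal, so both
   average and wide arrhythmic QRS complexes pass.
6. **R peaks.** Within each accepted block, the R peak is the sample with
   the largest $|x[n]|$; the absolute value makes inverted complexes free.

All five parameters are physical (Hz, ms, a fraction), converted to
samples per record, so the same settings apply to recordings from 128 Hz
to 1 kHz. The defaults are the exhaustive-search optimum on the MIT-BIH
Arrhythmia Database and should not normally be retuned per subject.

Because every quantity in the comparison scales by $c^2$ when the input is
scaled by $c$, and DC lies outside the passband, detections are invariant
to amplitude scaling and baseline offsets — properties the test suite
asserts exactly.

## Numerical choices

* **Window rounding.** Durations convert to samples by rounding half up
  (97 ms at 360 Hz → 35 samples, 611 ms → 220, 1 s → 360, 120 ms → 43,
  80 ms → 29). An `"odd"` mode that forces odd windows is available for a
  strictly centre-symmetric average, but the default reproduces the
  published sample counts, which include even optima such as 220.
* **Moving-average convention.** Windows are centred; an even window $w$
  spans $[n-w/2,\, n+w/2-1]$. At the record ends the window shrinks to the
  available samples and divides by the actual count, so constants are
  reproduced exactly and no artificial taper appears at the edges.
* **Edge transients.** The bidirectional filter sees one second of
  reflected signal at each end, trimmed after filtering.
* **Thresholds and ties.** Block membership uses strict `>`; width
  acceptance uses `>=`; the argmax inside a block breaks ties toward the
  earlier sample. $\bar z$ is the batch mean over the whole record —
  streaming operation is out of scope.
* **Degenerate inputs.** Records with non-finite samples are rejected
  outright rather than repaired; records shorter than one $W_2$ window are
  refused with the minimum duration in the message. Blocks touching the
  record ends are kept.
* **Idempotence caveat.** Refiltering an already-filtered signal is only
  a near-no-op for energy away from the band edges: a Butterworth passes
  $1/\sqrt2$ of the amplitude *at* the cutoff, so broadband content keeps
  shrinking there on repeated passes. The property tests therefore probe
  idempotence with mid-band sinusoids.

## Evaluation

Detections are matched to reference beats one-to-one by greedy
nearest-neighbour pairing within a tolerance window (default ±150 ms, the
conventional beat-matching window; the tolerance is configurable and
recorded in every report). Sensitivity $SE = TP/(TP+FN)$, positive
predictivity $+P = TP/(TP+FP)$, and overall accuracy is their arithmetic
mean. Zero-denominator cases are reported as `NA`, never as 0. Greedy
matching by increasing time difference makes the TP count monotone in the
tolerance, which the suite verifies on random instances.

## The optimizer

`brute_force_optimize()` enumerates every admissible combination of a
`parameter_grid()` ($f_1 < f_2$, $W_1 < W_2$), pools TP/FP/FN over the
corpus (database-level pooling, not per-record macro-averaging), and
returns the table sorted by descending overall accuracy. The default grid
mirrors the published search ranges: $f_1 \in 1\ldots10$ Hz,
$f_2 \in 11\ldots25$ Hz, $W_1 \in$ 55–111 ms, $W_2 \in$ 555–694 ms,
$\beta \in 0\ldots0.10$. Ties are broken by higher SE, then lower $W_1$,
lower $f_1$, lower $f_2$, lower $W_2$, lower $\beta$ — the last three keys
extend the natural tie-break into a total order, so the winning row is
independent of grid ordering even when many combinations are perfect on a
clean corpus. Preprocessing is cached per frequency band and moving
averages per window length; results are identical to running the detector
combination by combination.

## The Pan-Tompkins comparator

For side-by-side evaluation the package ships the classic adaptive
detector: resample to 200 Hz (its filters' design rate), mean
subtraction, 5–15 Hz band-pass, five-point derivative, squaring, 150 ms
moving integration, then dual signal/noise running thresholds
(0.125/0.875 level updates, threshold = noise + 0.25 × (signal − noise)),
a 200 ms refractory spacing, and a search-back pass at half threshold
when an RR interval exceeds 166% of the running average. The first two
seconds initialize the levels, so up to two warm-up beats may be missed
on a cold start. Detections are mapped back to the original sampling
grid and snapped to the nearest filtered extremum within ±25 ms. This is
a faithful functional implementation of the published rules, not a
bit-exact replica of the 1985 integer code.

## The synthetic generator

`generate_ecg()` renders a beat train of Gaussian pulses with
knowledge-base default durations (P 110 ms, PR 160 ms, QRS 100 ms; widths
interpreted as ±2σ spans) at a fixed heart rate or a linear ramp, with
Gaussian RR jitter truncated at ±3σ. The T wave follows each R peak at
min(300 ms, 0.45 RR), shortening at fast rates as real QT intervals do.
Noise is added *after* the ground-truth R indices are extracted from the
clean signal, so truth is exact by construction: 60 Hz mains with second
and third harmonics (rendered only below Nyquist), sub-1 Hz sinusoidal
baseline wander, and white Gaussian muscle noise. Morphology flags cover
inverted, biphasic (derivative-of-Gaussian) and widened complexes; a
widened QRS keeps a sharp apex over a doubled-width base, as bundle
branch block beats do — a *purely* wide Gaussian would be spectrally
empty above 8 Hz and invisible to any band-pass detector, which is an
artefact of the pulse model, not a property of real wide beats.

What the generator does *not* emulate: real QRS micro-structure
(notching, slurs), ectopic morphology families, electrode pops, pacing
artefacts, or non-stationary noise. Perfect scores on these fixtures
demonstrate the detector's contracts (scale/DC invariance, block logic,
localization), not database-level performance on clinical recordings;
benchmarking against PhysioNet databases requires downloading them and
feeding the WFDB files through `read_signal()`/`read_annotations()`.

The generator's defaults are the study conditions used throughout the
tests: 30 s records at 360 Hz and 60 bpm with unit QRS amplitude, and the
noise presets in `fixture_preset()` (e.g. mains 0.2 mV with 0.1/0.05
harmonics, muscle noise σ = 0.1 mV) chosen once as typical moderate
contamination levels relative to a 1 mV QRS.

## Problem sizes used in the shipped tests

The test suite exercises: the clean-signal sweep at 40–180 bpm ×
{128, 250, 360, 500, 1000} Hz on 20 s records; oracle-equivalence checks
on over 1000 random instances against naive reference implementations;
a 144-combination grid recovery on a 5 × 15 s corpus; and a 5-level
noise-degradation trend on 60 s records. These sizes were chosen so the
whole suite completes in well under a minute on a laptop while still
covering every contract; all of them scale up by changing one argument.

## Known limitations

* Batch, not streaming: $\bar z$ needs the whole record.
* No beat classification, P/T/U delineation, or rhythm analysis.
* The 1-based sample-index convention follows R; WFDB annotation files
  (0-based on disk) are converted on read and write.
* WFDB support covers headers plus signal formats 16 and 212 and the MIT
  annotation format — enough for the standard arrhythmia databases, not
  the whole format family.

## A worked run

```{r example}
syn <- generate_ecg(synthetic_spec(duration_s = 30, heart_rate_bpm = 72,
                                   muscle_noise_sd = 0.05,
                                   rr_jitter_sd_ms = 20, seed = 42))
det <- detect_qrs(syn$record)
det
evaluate_detection(det$r_peaks, syn$true_r_peaks, fs = syn$record$fs)
```
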