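---
title: "Ear-EEG sleep staging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ear-EEG sleep staging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earsleep)
```

## The problem

Clinical sleep staging rests on polysomnography (PSG): scalp EEG, EOG
and more, applied by trained personnel in a laboratory. A C-shaped
flex-printed electrode array worn around the ear (cEEGrid, channels
`R1`..`R8` against a right-mastoid reference) promises sleep EEG that
people can wear at home, but its electrodes sit far from the scalp
positions scoring conventions are written for. Two questions follow:

1. **Agreement.** If an expert scores hypnograms from ear-electrode
   derivations instead of a frontal reference montage (Fpz + two EOG
   channels), how well do the hypnograms agree, overall and per stage?
2. **Topography.** Which single or bipolar ear-channel combination best
   reproduces the frontal waveform of the N2 grapho-elements
   (K-complexes and sleep spindles) that scorers rely on?

`earsleep` implements both analyses end to end, plus the synthetic
full-night generator used to exercise them, since home recordings of
this kind are not generally redistributable.

## Virtual montages

Ear channels are combined linearly and relabeled after the PSG position
they extrapolate toward (all referenced to the right mastoid M2):

| virtual channel | combination |
|---|---|
| `Fp2_M2` | `R1` |
| `F4_M2`  | `(R1 + R2)/2 - R6` |
| `C4_M2`  | `(R2 + R3)/2 - (R6 + R7)/2` |
| `P4_M2`  | `(R3 + R4)/2 - R7` |
| `O2_M2`  | `R7 - R8` |

`R1` is already mastoid-referenced at acquisition, so `Fp2_M2` carries
no re-reference term; every other EEG derivation has zero-sum weights.
The `cEEGrid+EOG` layout adds `EOG_L - R6` and `EOG_R - R6`, using `R6`
as a stand-in mastoid for the periocular channels. Weights are exact
rationals (±1, ±0.5) applied in floating point; bipolar pairs are not
renormalized.

## Preprocessing

The conditioning chain is a zero-phase ("phase true") 4th-order
Butterworth bandpass, 0.5–40 Hz, followed by decimation from 250 Hz to
125 Hz.

* **Zero phase** is implemented as forward-backward application of the
  causal design, the standard reading. This squares the magnitude
  response, so each corner sits at −6 dB rather than −3 dB.
* **Edge handling.** Startup transients are suppressed by odd-symmetric
  (point-reflected) extension at both ends before filtering. The
  extension length is six cycles of the low cutoff
  (`ceiling(6 * fs / low_hz)`, capped at `n − 1`): the 0.5 Hz high-pass
  pole decays over seconds, so a pad sized in multiples of the filter
  order would leave visible forward/backward asymmetry at the record
  edges. With the six-cycle pad, filtering commutes with time reversal
  to better than 1e−6 (relative to the signal SD), which the test
  suite asserts.
* **Decimation** keeps every second sample without an extra anti-alias
  stage: the 40 Hz low-pass already bounds content far below the new
  62.5 Hz Nyquist. The suite verifies that decimation preserves
  per-tone amplitudes of the filtered signal within 5% across
  1–35 Hz. Note that the *filter itself* is only 5%-flat up to roughly
  25 Hz; between 25 Hz and the 40 Hz corner any Butterworth band edge
  rolls off smoothly (|H|² ≈ 0.78 at 35 Hz), which is a property of
  the published design, not of this implementation.

## Correlation topography

Grapho-element epochs are cut at the annotated onset/offset exactly
(variable length, no padding), the per-epoch mean is subtracted from
every trace, and the Fpz reference trace is correlated (Pearson; the
Fisher transform presumes it) against the derived trace of each of the
36 combinations — 8 singletons and 28 bipolar pairs in the conventional
interleaved order `R1, R1-R2, R2, R1-R3, ...`. Averages over epochs
(and over participants for a grand average) are taken on the Fisher-Z
scale: `tanh(mean(atanh(r)))`. Correlations of exactly ±1 are clipped
to ±(1 − 1e−12) before `atanh`; undefined correlations (zero-variance
traces) are reported as missing and excluded from averages, never
imputed as 0.

## Agreement statistics

Hypnograms are aligned epochwise (truncating to the shorter night, with
an optional `max_epochs` cap for partially unusable recordings — 5 h
20 min corresponds to 640 epochs of 30 s), cross-tabulated into a 6×6
confusion matrix over the canonical stage order
`Art, W, N1, N2, N3, REM`, and summarized by Cohen's κ:
`κ = (po − pe) / (1 − pe)`. Design choices:

* **Artifact epochs** are retained as a sixth category in the
  multi-class κ and counted in "rest" for the one-vs-rest collapse.
  This is the only convention under which the bundled reference
  confusion matrices reproduce their published κ table cell by cell.
* **Cohort-level κ** is computed on concatenated epochs (equivalently,
  on the summed confusion matrices — the suite asserts this identity),
  not as a mean of per-participant κs. Per-participant κs feed the
  paired one-tailed t-test comparing montage conditions.
* **Standard error** uses the Fleiss–Cohen–Everitt asymptotic variance
  for unweighted κ. Published SEs for comparable tables are given to
  2 decimals only, so SEs are checked to order of magnitude, not as
  exact targets.
* **Rounding** for comparison with 2-decimal printed values is half
  away from zero (`round_half_up`), matching how such tables are
  produced.
* **Degenerate paired t-test.** If the per-participant differences have
  zero variance the t statistic is undefined. The boundary case of
  identical inputs returns the no-effect limit `t = 0, p = 0.5`; a
  nonzero constant difference raises a degenerate-test error, since
  reporting `p → 0` from zero variance would overstate the evidence.

Verbal labels follow the Landis–Koch bands: ≤ 0 poor, (0, 0.20] slight,
(0.20, 0.40] fair, (0.40, 0.60] moderate, (0.60, 0.80] substantial,
(0.80, 1] almost perfect.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
not the full physiology of sleep EEG.

* **Hypnogram**: a first-order Markov chain over the six stages at 30-s
  epochs, started in wake, with strong self-transitions
  (`default_stage_transition()`), yielding realistic bout structure and
  a stage mix of roughly 40–45% N2 over a night.
* **Signals**: one frontal source drives all channels. Per stage it is
  an AR(1) background plus an AASM-conventional oscillation (10 Hz
  alpha in W, 5 Hz theta in N1, 1.25 Hz delta of 120 µV in N3, 7 Hz
  low-amplitude activity in REM, broadband bursts in Art). N2 epochs
  receive Hann-windowed 13 Hz spindles (0.5–2 s, 40 µV, 2.5/min) and
  biphasic K-complexes (0.5–1 s, 150 µV, 1.5/min), placed uniformly and
  non-overlappingly within the epoch by rejection sampling. REM epochs
  add opposite-polarity step deflections to `EOG_L`/`EOG_R`.
* **Mixing**: channel = gain × source + white sensor noise (15 µV SD, a
  realistic ambulatory noise floor). `Fpz` defines the source
  (gain 1). The ear gains are U-shaped around the C of the grid
  (`0.90, 0.55, 0.05, −0.35, −0.25, −0.08, 0.18, 0.42` for `R1`..`R8`):
  the anterior-superior (`R1`, `R2`) and anterior-inferior (`R7`, `R8`)
  ends face Fpz and see the frontal dipole with positive sign, while
  the posterior electrodes (`R4`, `R5`) see its inverted far field. A
  *monotone* front-to-rear gain profile cannot reproduce the observed
  directional topography — it would force every `Ri−Rj` (i < j)
  contrast positive — so the U-shape is the minimal geometry consistent
  with front-pointing combinations (`R1`, `R1-R4`) being maximally
  positive and rear-pointing ones (`R5-R8`, `R6-R8`) negative.
* **Second scorer**: each epoch is independently relabeled with
  probability `error_prob` (default 0.12) through an adjacent-stage
  biased, zero-diagonal kernel. Because the kernel never reproduces the
  true label, observed agreement is exactly `1 − error_prob`, and the
  expected κ has the closed form implemented in
  `expected_corruption_kappa()` (at `error_prob = 1` this is slightly
  *below* zero, `−pe/(1 − pe)`, not chance level).

What passing tests on this generator do and do not show: they validate
the pipeline's algebra (montage arithmetic, epoching, Fisher
averaging, κ computation) and the qualitative directional finding under
a known ground truth. They do not certify performance on real
ear-EEG — real recordings have multiple sources, non-stationary
artifacts, electrode drift and scorer biases that a single-dipole
white-noise model deliberately omits, and published correlation
magnitudes depend on those data. The numeric anchors the package *does*
reproduce exactly are the published confusion-matrix κ statistics,
which are functions of printed counts.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full synthetic loop at
20 nights of 1 h each (120 epochs, 250 Hz, 11 channels) for the
directional-topography property, 10,000 epochs for scorer-noise κ
recovery, and 30–40 s probes for the filter figures; these sizes give
stable statistics (topography signs are ≥ 4 SD from zero at the
smallest gain contrast) while keeping a laptop run in minutes. EDF
output digitizes to 16 bits over a per-channel symmetric physical range
with 0.01% headroom, so round trips are exact to within one
quantization step (about 0.004 µV at ±120 µV). One borderline printed
value deserves note: the per-stage κ of N1 in the ear+EOG comparison
computes to 0.41495 from the published counts, which a single half-up
rounding shows as 0.41 while the source table prints 0.42 (a
double-rounding of 0.415); the tests assert the computed value.

## Known limitations

* Single-source mixing cannot express combination-specific waveform
  distortions; correlation magnitudes on synthetic data are higher than
  on real recordings.
* The EDF layer writes plain continuous EDF (1-s records, one sampling
  rate) and does not parse EDF+ annotation channels.
* Only the right-ear grid (`R1`..`R8`) is modeled; left-ear and
  cross-ear layouts are out of scope.
* Automatic spindle/K-complex *detection* is out of scope: events enter
  as annotations, human or simulated.
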