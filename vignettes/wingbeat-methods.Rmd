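---
title: "Wing-beat signal analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wing-beat signal analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingbeatr)
```

## The measurement problem

An infrared light curtain across the entrance of a baited trap produces a
current that varies when a passing fly's wings partially occlude the beam.
Digitized through a sound-card line input, the result is a mono waveform,
amplitude-normalized to [−1, 1], in which each passage appears as a short
burst whose fundamental frequency is the insect's wing-beat frequency — a
physiological trait that separates *Anastrepha fraterculus* (fundamental
near 114 Hz) from *Ceratitis capitata* (near 161 Hz). The absolute
amplitude carries no calibrated meaning (gain and coupling are arbitrary),
so every statistic downstream is either a frequency, a duration, or a
dimensionless ratio.

The package implements four stages — passage detection, feature
extraction, species characterization, discrimination — plus a simulator
that stands in for the sensor. This vignette records the models, the
parameters that matter, and the choices made where the design was
genuinely open.

## Passage detection

The track is profiled with a sliding-window RMS (30 ms window, 10 ms
overlap, hence a 20 ms hop) and a passage is a maximal run of windows
whose RMS exceeds a threshold. Two points needed a decision:

* **Hop semantics.** "30 ms window with 10 ms overlap" is read as a 20 ms
  hop; configuring `overlap_ms = 20` gives the 10 ms-hop alternative.
* **Threshold scale.** A fixed threshold of 1 is unsatisfiable for the RMS
  of a [−1, 1] signal, so the threshold is configuration: either an
  absolute RMS value, or `"auto"` = `auto_k` × median window RMS
  (default `auto_k = 5`). The median is a robust noise-floor estimate:
  passages are rare, so the median window is background. With the
  simulator's default background (σ = 0.005) the auto threshold sits near
  0.03, an order of magnitude below typical event RMS and an order above
  the noise floor.

Event bounds are resolved at window granularity; no sub-window
refinement is attempted because 20 ms localization error is negligible
relative to the 100 ms duration criterion. Runs separated by at most
`merge_gap_ms` are merged (default 0 — no merging). Each stored event
keeps `pad_ms = 50` ms of context on each side.

The *standard group* used for characterization requires (a) core duration
≥ 100 ms (padding excluded) and (b) a direct passage. Direct passage was
a manual judgment in field practice — an indirect passage shows a
mid-event collapse of signal strength. The package operationalizes it as
a dip criterion: no interior RMS window of the event (first and last
window excluded, since they straddle the rise and fall) may drop below
`dip_fraction = 0.5` of the event's peak RMS. Events failing either rule
are kept with a `rejection_reason` ("duration", "dip") rather than
discarded, so provenance is auditable.

## Feature extraction

Each stored event is tapered with the 4-term Blackman–Harris window
(coefficients 0.35875, 0.48829, 0.14128, 0.01168; −92 dB sidelobes),
which suppresses the spectral leakage caused by clipping the event out of
the track. Two analysis paths follow.

**Autocorrelation.** The raw, unnormalized sum r(l) = Σᵢ x(i+l)·x(i) is
scanned over positive lags and the maximal lag gives the fundamental
period. Two departures from a naive maximum were required:

* The search is restricted to the physiological band 70–500 Hz
  (lags fs/500 … fs/70). Without a lower lag bound the zero-lag mainlobe
  always wins; without the band the estimate could leave the plausible
  wing-beat range entirely.
* r(l) is used exactly as the raw sum, without lag normalization.
  Finite-length decay slightly favors shorter lags, which is the desired
  tie-break between a period and its multiples.

At fs = 19 200 and F0 ≤ 200 Hz the lag quantization error is below 1 Hz.
The estimate fails toward *half* the true frequency when a subharmonic or
strong even-harmonic structure makes the doubled period dominate — a
documented failure mode, reproduced in the tests by construction.

**Zero-padded FFT.** The windowed event is padded with zeros to a whole
number of seconds, giving exactly 1 Hz bins for events shorter than 1 s
(longer events pad to the next whole second and get finer bins rather
than being truncated). The fundamental is the largest in-band magnitude
(band 70–1000 Hz); components F1–F4 are the four largest strict local
maxima above it, subject to two guards the source procedure leaves
unspecified:

* `min_separation_hz = 10`: picked peaks must be at least 10 Hz apart
  (and above F0 by at least that much), so near-mainlobe structure cannot
  register as a component;
* `min_rel_magnitude = 1e-3`: a component must be within 60 dB of the
  fundamental, so the −92 dB window sidelobes of an isolated tone are not
  promoted to components.

Peaks are reported at bin centers (integer Hz at 1 Hz resolution) without
parabolic interpolation, matching the integer-valued reporting convention
of the characterization tables. The FFT path fails toward *double* the
true frequency when M1 > M0 — also reproduced in tests by construction.

Derived features per event: F0 (autocorrelation), F0 (FFT), F1 − F0, the
ratios M0/Mk and differences Fk − F0 for k = 2..4, each with a validity
flag. All frequencies and magnitude *ratios* are invariant to amplitude
scaling of the event.

## Characterization

Per feature and species, in order:

1. **Octave-error gate** — a physiological validity band. Defaults:
   FFT-derived features of *A. fraterculus* gated above 200 Hz; of
   *C. capitata* to (70, 280) Hz; the autocorrelation feature ungated.
   These values mirror the observed error clusters: FFT peaks landing on
   the 2nd component sit near twice the species' fundamental, far outside
   these bands.
2. **Boxplot fences** — values strictly outside Q1 − 1.5·IQR or
   Q3 + 1.5·IQR are removed once (no iteration). Quartiles use linear
   interpolation between order statistics (R type 7); the hinge rule was
   unspecified upstream.
3. **Shapiro–Wilk gate** at p > 0.05. Failure produces a warning flag and
   the normal model is fitted anyway — after gating, residual
   non-normality is mild, and aborting would discard the feature entirely.
4. **Descriptive measures** — mean, SD and SE (n−1), bias-corrected
   *excess* kurtosis and skewness (type 2), range, min, max, n. Excess
   kurtosis is used because the reference values to compare against are
   near zero for normal-looking features.
5. **Student-t interval** — half width t₍(1+c)/2, n−1₎ · S/√n at
   confidence c = 0.95.

Provenance counts (events in, gated, fence-removed, used) are kept per
feature. A known irreproducibility: some reference half-widths (e.g.
±2.04 at n = 66, SD 7.97) cannot be recovered from the rounded SD and n
with any standard t quantile (which give ≈1.96); the package computes
strictly from its own data by the formula above, and its tests pin the
two half-widths that do reproduce exactly (2.63, 2.97).

## Discrimination

For each feature the boundary x\* is the root, strictly between the two
class means, of the quadratic obtained by equating the two normal
log-densities (the equal-SD case degenerates to the midpoint). Tails
beyond x\* under each model are the per-class misclassification
probabilities; for the two fundamental-frequency models they are below
1% (autocorrelation) and near 2–3% (FFT). Three open choices:

* **Combination rule.** "Use the three methods together" fixes no rule;
  the default is a majority vote of the three frequency features, with
  ties and vote-less events labeled `"unknown"` rather than forced. A
  summed-log-likelihood alternative is available (`rule = "likelihood"`).
* **Priors.** Equal class priors — the overlap probabilities are
  per-species conditionals, so the boundary is the density intersection,
  not a posterior-weighted one.
* **Feature exclusion.** Magnitude ratios do not vote: their class
  distributions (means ≈ 2.26 vs 2.05, SDs ≈ 0.75–0.96) overlap almost
  completely.

A vote is cast only if the feature value is valid and inside at least one
species' octave gate; values outside every gate are extraction errors,
not evidence.

## The simulator

`generate_event()` draws F0 from Normal(f0_mean, f0_sd) truncated at
zero, then synthesizes `n_components = 5` sinusoids at k·F0 with Gaussian
frequency jitter (`inharmonicity_sd = 1` Hz) and random phases. The
M0/M1 ratio is drawn near the species mean (2.26 for *A. fraterculus*,
2.05 for *C. capitata*; draws truncated at 1.05 so the fundamental stays
dominant by default), with geometric decay 0.6 for higher components. The
envelope is a cosine taper over 10% of the duration at each end — bursts
in real recordings rise quickly, and a long taper would trigger the dip
criterion designed for two-lobed indirect passages. Durations are uniform
on 0.18–0.35 s so that core durations clear the 100 ms standard-group
floor at window granularity; peak amplitude defaults to 0.5.

`generate_track()` places the configured number of events (default
30/min) at random non-overlapping times (minimum gap 0.25 s), over a
background of white noise (σ = 0.005), 60 Hz hum (amplitude 0.002) and a
slow drift sinusoid (amplitude 0.005, period 10 s) standing in for
luminosity fluctuations. The track is clipped to [−1, 1]; a single seed
fixes all randomness and the same configuration reproduces a
bit-identical track. Species-level defaults are the characterized
population models: Normal(113.75, 7.97) and Normal(160.81, 10.71) Hz.

`sensor_chain()` emulates the analog front end: 6th-order Butterworth
high-pass at 70 Hz and low-pass at 5 kHz, unit passband gain, applied
causally as the hardware does. The filters are realized as three cascaded
second-order sections designed from the analog prototype by bilinear
transform with prewarping — the digital counterpart of the hardware's
three cascaded 2nd-order MFB stages, and a numerical necessity: a direct
6th-order transfer function is unstable at the normalized cutoff that
70 Hz implies at 192 kHz. The ideal 6th-order high-pass attenuates 60 Hz
by ≈8.7 dB (−120 dB/decade asymptote), and that is what the
implementation delivers and the tests check.

**What the simulator does not emulate:** optical occlusion physics and
body-size effects near 0 Hz, phototransistor nonlinearity and the
high-frequency spectral degradation it causes (the reason components
F3–F4 are hard to locate in real recordings), amplifier noise beyond
additive white noise, and diurnal/behavioral structure in event timing.
Passing tests on synthetic data therefore demonstrate the correctness of
the algorithms under the stated signal model, not field performance.

## Numerical choices and degenerate inputs

* Integer PCM ↔ float convention: divide by 32768, so −32768 ↦ −1.0 and
  +32767 ↦ 0.99997; writing clips to [−1, 1] and saturates +1.0 at
  +32767. Round trips are exact to 1 LSB.
* Downsampling uses an 8th-order Butterworth at 80% of the new Nyquist,
  applied forward-backward (zero phase) so event timing does not shift,
  then decimates; it refuses factors that put the new rate below twice
  the 2 kHz analysis band edge.
* RMS windows are summed per window (not by cumulative-sum differencing)
  to keep the per-window error at machine precision regardless of track
  length.
* Constant samples are rejected by the Shapiro–Wilk gate; features with
  fewer than 4 valid values are dropped from a profile rather than
  fitted; classification with no usable feature returns `"unknown"`.
* Identical class models return misclassification probabilities
  (0.5, 0.5) by convention; a missing between-means density intersection
  (pathological SD ratio) is an error, not a silent fallback.

## Validation scale

The test suite validates parameter recovery at the study's own sample
sizes — 66 simulated *A. fraterculus* and 111 *C. capitata* passages at
fs = 19 200 (an integer divisor of the 192 kHz acquisition rate, fully
supported) — checking that recovered feature means fall within 3 SE of
the generating means and that the empirical two-species confusion matches
the Gaussian-overlap prediction within 3 Monte-Carlo SE. Larger-scale
quantities tied to the original 34 h of recordings (raw event counts per
species, appendix descriptive tables, recorded-data Shapiro–Wilk
p-values) have no released dataset to recompute from and are covered
instead by these property and recovery tests.

## Known limitations

* The dip criterion is a proxy for a manual judgment; its 0.5 fraction is
  a design choice, not a fitted value.
* Bin-center peak reporting quantizes FFT features to the bin grid
  (1 Hz); the autocorrelation feature is quantized by the lag grid
  (≈0.7 Hz near 114 Hz at fs = 19 200).
* The classifier is strictly two-species with equal priors; unknown
  species, multi-species mixtures and abundance-weighted priors are out
  of scope.
* Species profiles built from simulated data inherit the simulator's
  idealizations; profiles for field use should be rebuilt from real
  recordings via the same `build_profile()` path.
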