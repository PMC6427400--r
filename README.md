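# wingbeatr

Analysis of insect wing-beat signals recorded with an infrared
optoelectronic sensor, aimed at the automated monitoring of fruit-fly
(Diptera: Tephritidae) pests. The package detects fly passages in a
normalized sensor waveform, extracts the wing-beat fundamental frequency
and its harmonic components, characterizes a species' frequency
distribution statistically, and discriminates the two quarantine species
*Anastrepha fraterculus* (fundamental near 114 Hz) and *Ceratitis
capitata* (near 161 Hz) from the overlap of their per-feature normal
models. A seeded synthetic-signal simulator emulates passage events,
background noise, 60 Hz mains hum, slow luminosity drift and the sensor's
analog filter chain, so the whole pipeline can be exercised and validated
without hardware.

## The method

**Event detection.** The amplitude-normalized track x (samples in
[−1, 1]) is profiled by a sliding RMS window,

    RMS = sqrt( (1/n) * sum_i x_i^2 )

with a 30 ms window advancing by 20 ms (10 ms overlap). A passage event
is a maximal run of windows whose RMS exceeds a threshold (fixed, or
`auto` = 5 × the median window RMS); the stored event keeps 50 ms of
context on each side. Events enter the *standard group* used for
characterization only if the core duration is at least 100 ms and the
passage is direct — no interior window drops below half the event's peak
RMS.

**Feature extraction.** Each stored event is tapered with a 4-term
Blackman–Harris window and analyzed along two paths: (i) the raw
autocorrelation r(l) = Σ x(i+l) x(i), whose maximal lag inside the
70–500 Hz band gives the fundamental period T0 and frequency F0 = 1/T0;
(ii) a zero-padded FFT (padding to whole seconds gives 1 Hz bins) in
which the largest in-band magnitude is the fundamental F0 and the four
largest well-separated local maxima above it are components F1–F4 with
magnitudes M0–M4. Derived features: F0 (autocorrelation), F0 (FFT),
F1 − F0, and magnitude ratios M0/Mk.

**Characterization.** Per feature: physiological octave-error gating
(e.g. FFT peaks above 200 Hz for *A. fraterculus* are 2nd-component
mislocations, not biology), boxplot-fence outlier removal
(Q1 − 1.5·IQR, Q3 + 1.5·IQR), a Shapiro–Wilk normality gate (p > 0.05),
descriptive measures, and a Student-t confidence interval
IC(μ) = X̄ ± t·Sx. The result is a per-species profile of normal models
N(μ, σ) per feature.

**Classification.** For each feature the decision boundary x\* is the
abscissa between the class means where the two normal densities
intersect; the tails beyond x\* are the per-class misclassification
probabilities Pr(x₁ ≤ x ≤ x₂) under each model. Events are labeled by
majority vote of the three frequency features (magnitude ratios overlap
too much between the species to vote).

## Worked example

```r
library(wingbeatr)

cfg <- synth_config(seed = 42, event_rate = 30)   # 30 passages/min
mix <- list(
  list(params = species_defaults("fraterculus"), weight = 0.5, label = "fraterculus"),
  list(params = species_defaults("capitata"),    weight = 0.5, label = "capitata"))
sim <- generate_track(cfg, mix, 60)               # one minute of signal
sim$track
#> signal_track: 1152000 samples @ 19200 Hz ( 60 s )
#>   origin: synthetic[seed=42]

events <- detect_passages(sim$track)
sum(events$standard_group)
#> detected: 30 events; 30 in the standard group

feats <- event_features(events, sim$track$fs)
head(feats[, c("event_id", "f0_aut", "f0_fft", "f1_minus_f0", "mag_ratio_01")], 4)
#>   event_id   f0_aut f0_fft f1_minus_f0 mag_ratio_01
#> 1        1 119.2547    119         119     2.225376
#> 2        2 128.8591    129         128     2.272755
#> 3        3 153.6000    154         154     1.979024
#> 4        4 119.2547    120         118     2.389187

# overlap of the two characterized fundamental-frequency models
p <- misclassification_probs(normal_model(113.75, 7.97, 66),
                             normal_model(160.81, 10.71, 111))
sprintf("x* = %.2f Hz, p(A->C) = %.4f, p(C->A) = %.4f",
        p$x_star, p$p_low_as_high, p$p_high_as_low)
#> "x* = 134.36 Hz, p(A->C) = 0.0049, p(C->A) = 0.0068"
```

The three feature columns are the event's wing-beat fundamental
frequency in Hz by the autocorrelation and FFT paths and the spacing of
the 2nd spectral component above the fundamental; `mag_ratio_01` is
M0/M1. Classifying the 30 events against the two species models by the
fundamental frequency alone labels all 30 correctly (the species means
sit 47 Hz apart with SDs near 8–11 Hz, so the predicted confusion is
below 1%).

A pipeline-level interface with artifact files and provenance headers is
available through `pipeline_config()` / `run_pipeline()`, and as a shell
command in `inst/scripts/wingbeat.R`
(`Rscript wingbeat.R simulate --config cfg.json`).

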