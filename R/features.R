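# Automatic feature extraction from a stored event window: Blackman-Harris
# windowing, zero-padding to whole seconds (1 Hz FFT bins), fundamental
# frequency by autocorrelation, FFT magnitude spectrum and five-peak
# component picking, plus the derived per-event features used for species
# characterization (frequency differences and magnitude ratios).

#' Blackman-Harris window
#'
#' 4-term Blackman-Harris taper
#' w(n) = a0 - a1 cos(2 pi n/(N-1)) + a2 cos(4 pi n/(N-1)) - a3 cos(6 pi n/(N-1)),
#' n = 0..N-1. Applied to a stored event window it suppresses the spectral
#' leakage produced by clipping the event out of the track.
#'
#' @param n window length in samples (>= 2).
#' @param a the four coefficients (defaults 0.35875, 0.48829, 0.14128,
#'   0.01168).
#' @return numeric vector of window values.
#' @export
blackman_harris <- function(n, a = c(0.35875, 0.48829, 0.14128, 0.01168)) {
  if (n < 2L) stop("window length must be >= 2")
  k <- 2 * pi * (0:(n - 1L)) / (n - 1L)
  a[1L] - a[2L] * cos(k) + a[3L] * cos(2 * k) - a[4L] * cos(3 * k)
}

#' Apply a Blackman-Harris window to a waveform
#'
#' @param waveform numeric vector.
#' @param a window coefficients, see [blackman_harris()].
#' @return windowed waveform (elementwise product).
#' @export
apply_window <- function(waveform, a = c(0.35875, 0.48829, 0.14128, 0.01168)) {
  waveform * blackman_harris(length(waveform), a)
}

#' Zero-pad a waveform to whole seconds
#'
#' Appends zeros until the length is an integer number of seconds at `fs`,
#' so the FFT bin spacing becomes 1 Hz (or finer for events longer than one
#' second, which are padded to the next whole second).
#'
#' @param waveform numeric vector (the windowed event).
#' @param fs sampling rate, samples/s.
#' @return padded waveform with attribute `resolution_hz`.
#' @export
zero_pad_to_resolution <- function(waveform, fs) {
  n <- length(waveform)
  secs <- max(1L, as.integer(ceiling(n / fs)))
  target <- secs * as.integer(round(fs))
  out <- c(waveform, numeric(target - n))
  attr(out, "resolution_hz") <- fs / target
  out
}

#' Fundamental frequency by autocorrelation
#'
#' Computes the raw (unnormalized) autocorrelation r(l) = sum_i x(i+l) x(i)
#' for positive lags and returns the lag of maximal r within the period
#' range implied by `search_band` (default 70-500 Hz, the physiological
#' wing-beat band; the restriction excludes the zero-lag mainlobe, which
#' would otherwise always win). The fundamental period is the winning lag
#' in seconds and the fundamental frequency its reciprocal.
#'
#' @param waveform numeric vector (the windowed, un-padded event).
#' @param fs sampling rate, samples/s.
#' @param search_band c(f_lo, f_hi) in Hz.
#' @return list with `t0_aut` (s), `f0_aut` (Hz), `lag` (samples).
#' @export
autocorr_f0 <- function(waveform, fs, search_band = c(70, 500)) {
  n <- length(waveform)
  lag_min <- as.integer(ceiling(fs / search_band[2L]))
  lag_max <- as.integer(floor(fs / search_band[1L]))
  if (lag_min >= lag_max || lag_max >= n)
    stop("empty autocorrelation search band at fs = ", fs,
         " (need waveform longer than ", lag_max, " samples)")
  lags <- lag_min:lag_max
  r <- vapply(lags, function(l) sum(waveform[1:(n - l)] * waveform[(1L + l):n]), 0)
  best <- lags[which.max(r)]
  list(t0_aut = best / fs, f0_aut = fs / best, lag = best)
}

#' Magnitude spectrum of a padded event
#'
#' Discrete Fourier transform magnitudes for the non-negative frequencies;
#' with padding to whole seconds the bin spacing is `fs / length`.
#'
#' @param padded numeric vector from [zero_pad_to_resolution()].
#' @param fs sampling rate, samples/s.
#' @return list with `freq` (Hz), `mag`, `complex` (the DFT values) and
#'   `resolution_hz`.
#' @export
fft_spectrum <- function(padded, fs) {
  n <- length(padded)
  X <- stats::fft(padded)
  nk <- n %/% 2L + 1L
  res <- fs / n
  list(freq = (0:(nk - 1L)) * res, mag = Mod(X[1:nk]),
       complex = X[1:nk], resolution_hz = res)
}

#' Pick the fundamental and four components from a spectrum
#'
#' The fundamental (F0) is the frequency of the globally largest magnitude
#' inside `analysis_band`; among strict local maxima above F0 and separated
#' by at least `min_separation_hz` (from F0 and from each other), the four
#' of greatest magnitude become components F1-F4, reported in ascending
#' frequency. Missing components are flagged invalid (NA).
#'
#' @param spectrum output of [fft_spectrum()].
#' @param analysis_band c(f_lo, f_hi) in Hz (default 70-1000).
#' @param min_separation_hz minimum spacing between picked peaks (default
#'   10 Hz; prevents window sidelobes registering as components).
#' @param min_rel_magnitude magnitude floor for components, relative to the
#'   fundamental's magnitude (default 1e-3, i.e. -60 dB; local maxima below
#'   it, such as window sidelobes of an isolated tone, are not components).
#' @return a `component_set`: list with `f0_fft`, `m0`, `f` (F1..F4), `m`
#'   (M1..M4), `valid` (logical, per component).
#' @export
pick_components <- function(spectrum, analysis_band = c(70, 1000),
                            min_separation_hz = 10, min_rel_magnitude = 1e-3) {
  in_band <- which(spectrum$freq >= analysis_band[1L] &
                   spectrum$freq <= analysis_band[2L])
  if (length(in_band) < 3L) stop("empty analysis band")
  mag <- spectrum$mag
  i0 <- in_band[which.max(mag[in_band])]
  f0 <- spectrum$freq[i0]

  # strict local maxima above f0, inside the band
  cand <- in_band[-c(1L, length(in_band))]
  cand <- cand[mag[cand] > mag[cand - 1L] & mag[cand] > mag[cand + 1L]]
  cand <- cand[spectrum$freq[cand] > f0 &
               spectrum$freq[cand] >= f0 + min_separation_hz &
               mag[cand] >= min_rel_magnitude * mag[i0]]
  cand <- cand[order(mag[cand], decreasing = TRUE)]

  chosen <- integer(0)
  for (j in cand) {
    if (length(chosen) >= 4L) break
    if (all(abs(spectrum$freq[j] - spectrum$freq[chosen]) >= min_separation_hz))
      chosen <- c(chosen, j)
  }
  chosen <- chosen[order(spectrum$freq[chosen])]
  f <- rep(NA_real_, 4L); m <- rep(NA_real_, 4L)
  if (length(chosen) > 0L) {
    f[seq_along(chosen)] <- spectrum$freq[chosen]
    m[seq_along(chosen)] <- mag[chosen]
  }
  structure(list(f0_fft = f0, m0 = mag[i0], f = f, m = m, valid = !is.na(f)),
            class = "component_set")
}

#' Extract all features from one event
#'
#' Runs the two extraction paths on an event waveform: windowing then
#' autocorrelation for the fundamental period/frequency, and windowing,
#' zero-padding and FFT for the fundamental and components F1-F4 with
#' magnitudes M0-M4. Assembles the derived feature vector: F1 - F0
#' (frequency difference to the 2nd component), magnitude ratios M0/Mk and
#' frequency differences Fk - F0 for k = 2..4, with validity flags.
#'
#' @param waveform numeric event waveform (a padded event slice), or a row
#'   waveform from an `event_set`.
#' @param fs sampling rate, samples/s.
#' @param autocorr_band c(f_lo, f_hi) for the autocorrelation search.
#' @param analysis_band c(f_lo, f_hi) for FFT peak picking.
#' @param min_separation_hz minimum peak spacing, Hz.
#' @return list with `components` (`component_set` plus `t0_aut`, `f0_aut`)
#'   and `features` (named list: `f0_aut`, `f0_fft`, `f1_minus_f0`,
#'   `mag_ratio_01`, `mag_ratio_02`..., `f2_minus_f0`, ...).
#' @export
extract_features <- function(waveform, fs, autocorr_band = c(70, 500),
                             analysis_band = c(70, 1000),
                             min_separation_hz = 10) {
  if (length(waveform) < 2L) stop("empty event waveform")
  w <- apply_window(waveform)
  aut <- autocorr_f0(w, fs, autocorr_band)
  spec <- fft_spectrum(zero_pad_to_resolution(w, fs), fs)
  comp <- pick_components(spec, analysis_band, min_separation_hz)

  feats <- list(
    f0_aut = aut$f0_aut,
    t0_aut = aut$t0_aut,
    f0_fft = comp$f0_fft,
    f1_minus_f0 = if (comp$valid[1L]) comp$f[1L] - comp$f0_fft else NA_real_,
    mag_ratio_01 = if (comp$valid[1L]) comp$m0 / comp$m[1L] else NA_real_
  )
  for (k in 2:4) {
    feats[[paste0("f", k, "_minus_f0")]] <-
      if (comp$valid[k]) comp$f[k] - comp$f0_fft else NA_real_
    feats[[paste0("mag_ratio_0", k)]] <-
      if (comp$valid[k]) comp$m0 / comp$m[k] else NA_real_
  }
  comp$t0_aut <- aut$t0_aut
  comp$f0_aut <- aut$f0_aut
  list(components = comp, features = feats)
}

#' Extract features for every event of an event set
#'
#' @param events an `event_set` from [detect_passages()] or
#'   [detect_events()].
#' @param fs sampling rate of the source track.
#' @param standard_only restrict to standard-group events (default TRUE).
#' @param ... passed to [extract_features()].
#' @return data.frame, one row per event, with the event id and all derived
#'   features.
#' @export
event_features <- function(events, fs, standard_only = TRUE, ...) {
  stopifnot(inherits(events, "event_set"))
  wv <- attr(events, "waveforms")
  idx <- seq_len(nrow(events))
  if (standard_only && nrow(events) > 0L)
    idx <- idx[which(events$standard_group)]
  rows <- lapply(idx, function(i) {
    fx <- extract_features(wv[[i]], fs, ...)$features
    c(list(event_id = events$event_id[i]), fx)
  })
  if (length(rows) == 0L) {
    proto <- c(list(event_id = integer(0)),
               stats::setNames(rep(list(numeric(0)), 11L),
                 c("f0_aut", "t0_aut", "f0_fft", "f1_minus_f0", "mag_ratio_01",
                   "f2_minus_f0", "mag_ratio_02", "f3_minus_f0", "mag_ratio_03",
                   "f4_minus_f0", "mag_ratio_04")))
    return(as.data.frame(proto))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
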