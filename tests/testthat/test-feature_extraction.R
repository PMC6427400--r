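test_that("Blackman-Harris window has the documented edge and center values", {
  for (n in c(101, 256)) {
    w <- blackman_harris(n)
    expect_equal(w[1], 0.35875 - 0.48829 + 0.14128 - 0.01168, tolerance = 1e-12)
    expect_equal(w[1], 6e-5, tolerance = 1e-6)
    expect_equal(w, rev(w))                       # symmetry w(n) = w(N-1-n)
  }
  w <- blackman_harris(101)
  expect_equal(w[51], 0.35875 + 0.48829 + 0.14128 + 0.01168, tolerance = 1e-12)
  expect_equal(w[51], 1, tolerance = 1e-5)
  expect_error(blackman_harris(1), ">= 2")
})

test_that("windowing reduces leakage of an off-bin tone", {
  fs <- 19200
  x <- make_tone(150.5, fs, 0.3)
  sidelobe <- function(sig) {
    spec <- fft_spectrum(zero_pad_to_resolution(sig, fs), fs)
    away <- spec$freq > 50 & spec$freq < 1000 & abs(spec$freq - 150.5) > 20
    max(spec$mag[away]) / max(spec$mag)
  }
  expect_lt(sidelobe(apply_window(x)), sidelobe(x))
})

test_that("zero padding reaches whole seconds, 1 Hz bins, and keeps energy", {
  fs <- 19200
  x <- make_tone(110, fs, 0.3)
  p <- zero_pad_to_resolution(x, fs)
  expect_length(p, 19200)
  expect_equal(attr(p, "resolution_hz"), 1)
  expect_identical(p[seq_along(x)], x)
  expect_equal(sum(p^2), sum(x^2))
  # events longer than 1 s pad to the next whole second, finer bins
  y <- make_tone(110, fs, 1.3)
  p2 <- zero_pad_to_resolution(y, fs)
  expect_length(p2, 2 * fs)
  expect_equal(attr(p2, "resolution_hz"), 0.5)
})

test_that("autocorrelation finds the exact period of a pure tone", {
  fs <- 19200
  x <- make_tone(100, fs, 0.3)
  res <- autocorr_f0(x, fs)
  expect_identical(res$lag, 192L)
  expect_equal(res$t0_aut, 0.01)
  expect_equal(res$f0_aut, 100)
  # brute-force lag scan agrees
  expect_identical(res$lag, as.integer(oracle_autocorr_lag(x, fs)))
  # frequency is the exact reciprocal of the period
  expect_equal(res$f0_aut, 1 / res$t0_aut)
})

test_that("a 9.12 ms fundamental period maps to 109.65 Hz", {
  fs <- 25000  # 9.12 ms is exactly 228 samples at this rate
  burst <- make_harmonic_burst(1 / 0.00912, c(1, 0.45, 0.25), fs, 0.3)
  res <- autocorr_f0(apply_window(burst), fs)
  expect_identical(res$lag, 228L)
  expect_equal(res$t0_aut, 0.00912)
  expect_equal(round(res$f0_aut, 2), 109.65)
})

test_that("FFT spectrum satisfies Parseval and linearity", {
  fs <- 19200
  set.seed(41)
  x <- zero_pad_to_resolution(runif(5000, -1, 1), fs)
  spec <- fft_spectrum(x, fs)
  n <- length(x)
  # reassemble the full-spectrum energy from the half spectrum
  interior <- 2:(n %/% 2)
  energy <- spec$mag[1]^2 + spec$mag[n %/% 2 + 1]^2 + 2 * sum(spec$mag[interior]^2)
  expect_equal(energy / n, sum(x^2), tolerance = 1e-9)

  y <- zero_pad_to_resolution(runif(5000, -1, 1), fs)
  sx <- fft_spectrum(x, fs); sy <- fft_spectrum(y, fs)
  sxy <- fft_spectrum(x + y, fs)
  expect_equal(sxy$complex, sx$complex + sy$complex, tolerance = 1e-9)

  tone <- fft_spectrum(zero_pad_to_resolution(make_tone(150, fs, 1), fs), fs)
  expect_equal(tone$freq[which.max(tone$mag)], 150)
})

test_that("component picking recovers constructed harmonics", {
  fs <- 19200
  x <- make_harmonic_burst(110, c(1, 0.5, 0.35, 0.25, 0.18), fs, 0.4)
  spec <- fft_spectrum(zero_pad_to_resolution(apply_window(x), fs), fs)
  comp <- pick_components(spec)
  expect_equal(comp$f0_fft, 110, tolerance = 1)
  expect_true(all(comp$valid))
  expect_equal(comp$f, c(220, 330, 440, 550), tolerance = 1)
  expect_true(all(diff(c(comp$f0_fft, comp$f)) > 0))

  # a pure tone has a fundamental and no components
  tone <- fft_spectrum(zero_pad_to_resolution(apply_window(
    make_tone(150, fs, 0.3)), fs), fs)
  solo <- pick_components(tone)
  expect_equal(solo$f0_fft, 150, tolerance = 1)
  expect_false(any(solo$valid))
})

test_that("a dominant 2nd component produces the documented octave error", {
  fs <- 19200
  x <- make_harmonic_burst(110, c(0.4, 1, 0.2), fs, 0.3)
  spec <- fft_spectrum(zero_pad_to_resolution(apply_window(x), fs), fs)
  comp <- pick_components(spec)
  expect_equal(comp$f0_fft, 220, tolerance = 1)
})

test_that("even-harmonic dominance halves the autocorrelation estimate", {
  fs <- 19200
  # strong 160 Hz + weak 80 Hz subharmonic: wing-beat F0 is 160, but the
  # true period of the summed signal is 1/80 s
  t <- seq(0, 0.3 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 160 * t) + 0.2 * sin(2 * pi * 80 * t)
  res <- autocorr_f0(apply_window(x), fs)
  expect_equal(res$f0_aut, 80, tolerance = 1)
})

test_that("full extraction recovers a 160 Hz event within 2 Hz", {
  set.seed(17)
  fs <- 19200
  p <- species_synth_params(f0_mean = 160, f0_sd = 1e-9, inharmonicity_sd = 0,
                            mag_ratio_mean = 2.26, mag_ratio_sd = 1e-9,
                            duration_range = c(0.3, 0.3))
  ev <- generate_event(p, fs)
  noisy <- ev$waveform + rnorm(length(ev$waveform), 0, 0.005)
  fx <- extract_features(noisy, fs)$features
  expect_lt(abs(fx$f0_aut - 160), 2)
  expect_lt(abs(fx$f0_fft - 160), 2)
  expect_lt(abs(fx$f1_minus_f0 - 160), 2)
  expect_lt(abs(fx$mag_ratio_01 - 2.26) / 2.26, 0.1)
})

test_that("features are invariant to amplitude scaling", {
  set.seed(18)
  fs <- 19200
  x <- make_harmonic_burst(113, c(1, 0.45, 0.3), fs, 0.25) +
    rnorm(round(0.25 * fs), 0, 0.003)
  a <- extract_features(x, fs)$features
  b <- extract_features(0.31 * x, fs)$features
  for (fn in c("f0_aut", "f0_fft", "f1_minus_f0", "mag_ratio_01",
               "mag_ratio_02", "f2_minus_f0"))
    expect_equal(a[[fn]], b[[fn]], tolerance = 1e-9)
})

test_that("degenerate inputs are rejected cleanly", {
  expect_error(extract_features(numeric(1), 19200), "empty")
  expect_error(autocorr_f0(make_tone(100, 19200, 0.005), 19200), "search band")
  expect_error(pick_components(
    fft_spectrum(zero_pad_to_resolution(make_tone(100, 19200, 0.1), 19200), 19200),
    analysis_band = c(900, 901)), "empty")
})
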