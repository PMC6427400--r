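# Signal fixtures and brute-force oracles shared across tests.

make_tone <- function(freq, fs, dur_s, amp = 0.5, phase = 0) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

# Harmonic burst: components at multiples of f0 with given amplitudes,
# cosine-tapered envelope, peak scaled to `amp`.
make_harmonic_burst <- function(f0, amps, fs, dur_s, amp = 0.5,
                                taper = 0.1, phases = NULL) {
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  if (is.null(phases)) phases <- rep(pi / 2, length(amps))
  x <- numeric(n)
  for (k in seq_along(amps))
    x <- x + amps[k] * sin(2 * pi * k * f0 * t + phases[k])
  ramp_n <- max(2, round(n * taper))
  env <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = ramp_n)))
  env[seq_len(ramp_n)] <- ramp
  env[n - seq_len(ramp_n) + 1] <- ramp
  x <- x * env
  x / max(abs(x)) * amp
}

# Track with bursts at given start times over gaussian noise.
make_burst_track <- function(bursts, starts_s, fs, length_s, noise_sd = 0.005,
                             seed = 1) {
  set.seed(seed)
  n <- round(length_s * fs)
  x <- rnorm(n, 0, noise_sd)
  for (i in seq_along(bursts)) {
    i0 <- round(starts_s[i] * fs) + 1
    idx <- i0:(i0 + length(bursts[[i]]) - 1)
    x[idx] <- x[idx] + bursts[[i]]
  }
  signal_track(pmin(1, pmax(-1, x)), fs, origin = "test")
}

# Independent brute-force RMS profile (explicit per-window loop).
oracle_rms <- function(x, fs, window_ms = 30, overlap_ms = 10) {
  n_win <- round(window_ms / 1000 * fs)
  n_hop <- round((window_ms - overlap_ms) / 1000 * fs)
  starts <- seq(1, length(x) - n_win + 1, by = n_hop)
  sapply(starts, function(i) {
    w <- x[i:(i + n_win - 1)]
    sqrt(mean(w^2))
  })
}

# Independent brute-force autocorrelation lag scan.
oracle_autocorr_lag <- function(x, fs, band = c(70, 500)) {
  lags <- ceiling(fs / band[2]):floor(fs / band[1])
  best_lag <- NA
  best_r <- -Inf
  for (l in lags) {
    r <- 0
    for (i in 1:(length(x) - l)) r <- r + x[i + l] * x[i]
    if (r > best_r) {
      best_r <- r
      best_lag <- l
    }
  }
  best_lag
}

# Independent grid search for the between-means density intersection.
oracle_intersection <- function(mu1, sd1, mu2, sd2, step = 0.001) {
  lo <- min(mu1, mu2)
  hi <- max(mu1, mu2)
  grid <- seq(lo + step, hi - step, by = step)
  grid[which.min(abs(dnorm(grid, mu1, sd1) - dnorm(grid, mu2, sd2)))]
}

# t quantile by numeric integration of the t density (independent of qt).
oracle_t_quantile <- function(p, df) {
  uniroot(function(q)
    0.5 + integrate(function(x) dt(x, df), 0, q, rel.tol = 1e-10)$value - p,
    c(0, 50), tol = 1e-9)$root
}

# Spectral peak of a raw waveform (no windowing), frequency and amplitude.
oracle_peak <- function(x, fs) {
  X <- Mod(fft(x)) / length(x) * 2
  half <- 2:(floor(length(x) / 2))
  i <- half[which.max(X[half])]
  list(freq = (i - 1) * fs / length(x), amp = X[i])
}
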