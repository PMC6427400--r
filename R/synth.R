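# Synthetic wing-beat signal generator. Passage events are modeled as a sum
# of near-harmonic sinusoids (fundamental plus components near integer
# multiples, decaying magnitudes) shaped by a cosine-tapered envelope,
# embedded in white noise with optional 60 Hz mains hum and slow luminosity
# drift, optionally passed through the emulated analog sensor chain.

#' Species-level generative parameters for passage events
#'
#' The fundamental wing-beat frequency of each event is drawn from
#' Normal(`f0_mean`, `f0_sd`), truncated at zero. Spectral component k sits
#' near k*F0 with Gaussian jitter `inharmonicity_sd`. The fundamental-to-2nd
#' component magnitude ratio M0/M1 is drawn near `mag_ratio_mean`; magnitudes
#' of components 3..n decay geometrically by `mag_decay`.
#'
#' @param f0_mean mean fundamental frequency, Hz.
#' @param f0_sd SD of the fundamental frequency, Hz (> 0).
#' @param n_components number of spectral components including the
#'   fundamental (default 5).
#' @param mag_ratio_mean mean M0/M1 magnitude ratio (>= 1).
#' @param mag_ratio_sd SD of the M0/M1 ratio draw (draws truncated at 1.05).
#' @param mag_decay multiplicative magnitude decay for components >= 3.
#' @param inharmonicity_sd Hz jitter on component center frequencies.
#' @param duration_range (min_s, max_s) of the event envelope (min >= 0.05).
#' @param amplitude peak amplitude of the event waveform (<= 1).
#' @param taper_fraction fraction of the envelope spent in each cosine taper.
#' @return a `species_synth_params` list.
#' @export
species_synth_params <- function(f0_mean, f0_sd, n_components = 5L,
                                 mag_ratio_mean = 2, mag_ratio_sd = 0.2,
                                 mag_decay = 0.6, inharmonicity_sd = 1,
                                 duration_range = c(0.18, 0.35),
                                 amplitude = 0.5, taper_fraction = 0.1) {
  if (f0_sd <= 0) stop("'f0_sd' must be > 0")
  if (mag_ratio_mean < 1) stop("'mag_ratio_mean' must be >= 1")
  if (duration_range[1L] < 0.05) stop("duration_range min must be >= 0.05 s")
  if (diff(duration_range) < 0) stop("duration_range must be increasing")
  if (amplitude <= 0 || amplitude > 1) stop("'amplitude' must be in (0, 1]")
  structure(list(f0_mean = f0_mean, f0_sd = f0_sd,
                 n_components = as.integer(n_components),
                 mag_ratio_mean = mag_ratio_mean, mag_ratio_sd = mag_ratio_sd,
                 mag_decay = mag_decay, inharmonicity_sd = inharmonicity_sd,
                 duration_range = duration_range, amplitude = amplitude,
                 taper_fraction = taper_fraction),
            class = "species_synth_params")
}

#' Default generative parameters for the two study species
#'
#' Defaults encode the characterized populations: *Anastrepha fraterculus*
#' with fundamental frequency Normal(113.75, 7.97) Hz and M0/M1 ratio 2.26;
#' *Ceratitis capitata* with Normal(160.81, 10.71) Hz and ratio 2.05.
#'
#' @param species `"fraterculus"` or `"capitata"`.
#' @param ... overrides passed to [species_synth_params()].
#' @return a `species_synth_params`.
#' @export
species_defaults <- function(species = c("fraterculus", "capitata"), ...) {
  species <- match.arg(species)
  base <- switch(species,
    fraterculus = list(f0_mean = 113.75, f0_sd = 7.97, mag_ratio_mean = 2.26),
    capitata    = list(f0_mean = 160.81, f0_sd = 10.71, mag_ratio_mean = 2.05)
  )
  do.call(species_synth_params, utils::modifyList(base, list(...)))
}

#' Track-level simulator configuration
#'
#' @param fs sampling rate, samples/s (>= 4000).
#' @param noise_sd SD of the white background noise (amplitude units).
#' @param hum_amplitude amplitude of the 60 Hz mains hum.
#' @param drift_amplitude amplitude of the slow luminosity drift.
#' @param drift_period_s period of the drift sinusoid, seconds.
#' @param event_rate events per minute.
#' @param seed RNG seed fixing all randomness of the track.
#' @param sensor_chain_enabled apply the emulated analog front end.
#' @param min_gap_s minimum silent gap between events, seconds.
#' @return a `synth_config` list.
#' @export
synth_config <- function(fs = 19200, noise_sd = 0.005, hum_amplitude = 0.002,
                         drift_amplitude = 0.005, drift_period_s = 10,
                         event_rate = 30, seed = 1L,
                         sensor_chain_enabled = FALSE, min_gap_s = 0.25) {
  if (fs < 4000) stop("'fs' must be >= 4000")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(fs = fs, noise_sd = noise_sd, hum_amplitude = hum_amplitude,
                 drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s, event_rate = event_rate,
                 seed = as.integer(seed),
                 sensor_chain_enabled = isTRUE(sensor_chain_enabled),
                 min_gap_s = min_gap_s),
            class = "synth_config")
}

cosine_taper_envelope <- function(n, taper_fraction) {
  # Tukey-style envelope: cosine rise/fall over taper_fraction of the length.
  k <- max(2L, as.integer(round(n * taper_fraction)))
  env <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = k)))
  env[seq_len(k)] <- ramp
  env[n - seq_len(k) + 1L] <- ramp
  env
}

#' Generate one synthetic passage event
#'
#' Draws a fundamental frequency from the species model and synthesizes
#' `n_components` sinusoids at near-integer multiples with random phases and
#' decaying magnitudes, shaped by a cosine-tapered envelope, with the peak
#' scaled to the configured amplitude.
#'
#' @param params a [species_synth_params()].
#' @param fs sampling rate, samples/s.
#' @return list with `waveform` (numeric) and `truth` (list: `f0`,
#'   `duration_s`, `components` data.frame with `freq`, `amp`).
#' @export
generate_event <- function(params, fs) {
  stopifnot(inherits(params, "species_synth_params"))
  f0 <- -1
  while (f0 <= 0) f0 <- stats::rnorm(1L, params$f0_mean, params$f0_sd)
  dur <- stats::runif(1L, params$duration_range[1L], params$duration_range[2L])
  n <- max(2L, as.integer(round(dur * fs)))
  t <- (seq_len(n) - 1L) / fs

  nc <- params$n_components
  freqs <- f0 * seq_len(nc)
  if (nc > 1L && params$inharmonicity_sd > 0) {
    jit <- stats::rnorm(nc - 1L, 0, params$inharmonicity_sd)
    freqs[-1L] <- freqs[-1L] + jit
  }
  ratio <- max(1.05, stats::rnorm(1L, params$mag_ratio_mean, params$mag_ratio_sd))
  amps <- numeric(nc)
  amps[1L] <- 1
  if (nc >= 2L) amps[2L] <- 1 / ratio
  if (nc >= 3L)
    for (k in 3:nc) amps[k] <- amps[k - 1L] * params$mag_decay
  phases <- stats::runif(nc, 0, 2 * pi)

  x <- numeric(n)
  for (k in seq_len(nc)) x <- x + amps[k] * sin(2 * pi * freqs[k] * t + phases[k])
  x <- x * cosine_taper_envelope(n, params$taper_fraction)
  x <- x * (params$amplitude / max(abs(x)))
  list(waveform = x,
       truth = list(f0 = f0, duration_s = n / fs,
                    components = data.frame(freq = freqs, amp = amps)))
}

#' Generate a labeled synthetic sensor track
#'
#' Places passage events from a mixture of species at random non-overlapping
#' times over a background of white noise, 60 Hz hum and slow drift; clips
#' to \[-1, 1\] and optionally applies the emulated sensor chain. All
#' randomness is fixed by `config$seed`: the same configuration yields a
#' bit-identical track.
#'
#' @param config a [synth_config()].
#' @param species_mix list of `list(params =, weight =, label =)` entries;
#'   weights must sum to 1.
#' @param length_s track length in seconds.
#' @return list with `track` ([signal_track]) and `truth` (data.frame: one
#'   row per event with `label`, `f0`, `start_s`, `end_s`).
#' @export
generate_track <- function(config, species_mix, length_s) {
  stopifnot(inherits(config, "synth_config"))
  w <- vapply(species_mix, function(m) m$weight, 0)
  if (abs(sum(w) - 1) > 1e-8) stop("species weights must sum to 1")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  fs <- config$fs
  n_total <- as.integer(round(length_s * fs))
  n_events <- as.integer(round(config$event_rate * length_s / 60))

  events <- list()
  if (n_events > 0L) {
    which_sp <- sample.int(length(species_mix), n_events, replace = TRUE, prob = w)
    events <- lapply(which_sp, function(i)
      c(generate_event(species_mix[[i]]$params, fs),
        list(label = species_mix[[i]]$label)))
    durs <- vapply(events, function(e) e$truth$duration_s, 0)
    slack <- length_s - sum(durs) - (n_events + 1L) * config$min_gap_s
    if (slack < 0)
      stop("event rate too high: ", n_events, " events do not fit in ",
           length_s, " s without overlap")
    extra <- stats::runif(n_events + 1L)
    gaps <- config$min_gap_s + extra / sum(extra) * slack
    starts <- cumsum(gaps[seq_len(n_events)]) + c(0, cumsum(durs))[seq_len(n_events)]
  }

  t <- (seq_len(n_total) - 1L) / fs
  x <- stats::rnorm(n_total, 0, config$noise_sd)
  if (config$hum_amplitude > 0)
    x <- x + config$hum_amplitude * sin(2 * pi * 60 * t)
  if (config$drift_amplitude > 0)
    x <- x + config$drift_amplitude * sin(2 * pi * t / config$drift_period_s)

  truth <- data.frame(label = character(0), f0 = numeric(0),
                      start_s = numeric(0), end_s = numeric(0))
  for (i in seq_along(events)) {
    e <- events[[i]]
    i0 <- as.integer(round(starts[i] * fs)) + 1L
    idx <- i0:(i0 + length(e$waveform) - 1L)
    x[idx] <- x[idx] + e$waveform
    truth[i, ] <- list(e$label, e$truth$f0, (i0 - 1L) / fs,
                       (i0 - 1L + length(e$waveform)) / fs)
  }

  x <- pmin(1, pmax(-1, x))
  track <- signal_track(x, fs, origin = sprintf("synthetic[seed=%d]", config$seed))
  if (config$sensor_chain_enabled) track <- sensor_chain(track)
  list(track = track, truth = truth)
}
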