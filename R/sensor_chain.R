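# Digital emulation of the analog sensor front end: 6th-order Butterworth
# high-pass at 70 Hz (removes the DC level from the LED base light and
# attenuates 60 Hz mains) and 6th-order Butterworth low-pass at 5 kHz
# (anti-alias). Realized as cascaded second-order sections, the digital
# analogue of the hardware's three cascaded 2nd-order MFB stages; a direct
# 6th-order transfer function is numerically unstable at the low normalized
# cutoffs that a 192 kHz rate implies.

# Second-order sections of an even-order digital Butterworth filter,
# designed from the analog prototype by bilinear transform with prewarping.
butter_sos <- function(n, fc, fs, type = c("high", "low")) {
  type <- match.arg(type)
  if (n %% 2L != 0L) stop("only even filter orders are supported")
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  wc <- 2 * fs * tan(pi * fc / fs)  # prewarped analog cutoff (rad/s)
  k <- seq_len(n %/% 2L)
  theta <- pi * (2 * k - 1) / (2 * n) + pi / 2  # upper-half-plane prototype poles
  proto <- exp(1i * theta)
  lapply(proto, function(p) {
    s_pole <- if (type == "low") wc * p else wc / p
    zp <- (1 + s_pole / (2 * fs)) / (1 - s_pole / (2 * fs))
    a <- c(1, -2 * Re(zp), Mod(zp)^2)
    b <- if (type == "high") c(1, -2, 1) else c(1, 2, 1)
    z0 <- if (type == "high") -1 else 1  # frequency at which gain is pinned to 1
    gain <- sum(a * z0^(0:2)) / sum(b * z0^(0:2))
    list(b = b * gain, a = a)
  })
}

apply_sos <- function(sos, x) {
  for (sec in sos) x <- as.numeric(signal::filter(sec$b, sec$a, x))
  x
}

#' Emulate the analog sensor chain on a track
#'
#' Applies the digital realization of the sensor's analog conditioning: a
#' 6th-order Butterworth high-pass at `hp_hz` (default 70 Hz; unit passband
#' gain, suppresses DC and attenuates 60 Hz hum by about 8.7 dB) followed by
#' a 6th-order Butterworth low-pass at `lp_hz` (default 5000 Hz, anti-alias),
#' then clips to \[-1, 1\]. Filtering is causal, as in the hardware. The
#' low-pass stage requires `fs > 10000`; at lower rates it is skipped with a
#' warning (the band of interest is already below Nyquist).
#'
#' @param track a [signal_track].
#' @param hp_hz high-pass cutoff in Hz (default 70).
#' @param lp_hz low-pass cutoff in Hz (default 5000).
#' @param order filter order for each stage (even; default 6).
#' @return filtered `signal_track`.
#' @export
sensor_chain <- function(track, hp_hz = 70, lp_hz = 5000, order = 6L) {
  stopifnot(inherits(track, "signal_track"))
  x <- apply_sos(butter_sos(order, hp_hz, track$fs, "high"), track$samples)
  if (track$fs > 10000) {
    x <- apply_sos(butter_sos(order, lp_hz, track$fs, "low"), x)
  } else {
    warning("fs <= 10 kHz: low-pass stage skipped")
  }
  signal_track(pmin(1, pmax(-1, x)), track$fs,
               origin = paste0(track$origin, "[sensor_chain]"))
}
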