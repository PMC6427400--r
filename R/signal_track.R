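#' Construct a signal track
#'
#' A `signal_track` is a mono, amplitude-normalized sensor waveform together
#' with its sampling rate. All downstream stages (event detection, feature
#' extraction) operate on this container. Samples are dimensionless and must
#' lie in \[-1, 1\], the convention used when the sensor output is digitized
#' through a sound-card line input.
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\].
#' @param fs sampling rate in samples per second (> 0).
#' @param origin free-text provenance label (file path, simulator config, ...).
#'
#' @return an object of class `signal_track` with fields `samples`, `fs`,
#'   `origin`.
#' @export
signal_track <- function(samples, fs, origin = "") {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("'samples' must be a non-empty numeric vector")
  if (anyNA(samples))
    stop("'samples' contains NA")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  rng <- range(samples)
  if (rng[1L] < -1 || rng[2L] > 1)
    stop("samples must lie in [-1, 1]; got range [",
         signif(rng[1L], 6), ", ", signif(rng[2L], 6), "]")
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         origin = as.character(origin)[1L]),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$samples), "samples @", x$fs, "Hz (",
      signif(length(x$samples) / x$fs, 4), "s )\n")
  if (nzchar(x$origin)) cat("  origin:", x$origin, "\n")
  invisible(x)
}

#' Duration of a signal track in seconds
#' @param track a `signal_track`.
#' @return duration in seconds.
#' @export
track_duration <- function(track) length(track$samples) / track$fs

#' Split a track into consecutive chunks
#'
#' Long recordings (the field protocol stores one-hour tracks) are segmented
#' into non-overlapping chunks for processing. Concatenating the chunks
#' reproduces the input exactly; the final chunk may be shorter.
#'
#' @param track a `signal_track`.
#' @param chunk_s chunk length in seconds (> 0).
#' @return list of `signal_track` chunks.
#' @export
segment_track <- function(track, chunk_s) {
  stopifnot(inherits(track, "signal_track"))
  if (!is.numeric(chunk_s) || length(chunk_s) != 1L || chunk_s <= 0)
    stop("'chunk_s' must be a single positive number")
  n <- length(track$samples)
  step <- max(1L, as.integer(round(chunk_s * track$fs)))
  starts <- seq.int(1L, n, by = step)
  lapply(seq_along(starts), function(i) {
    from <- starts[i]
    to <- min(n, from + step - 1L)
    signal_track(track$samples[from:to], track$fs,
                 origin = sprintf("%s[chunk %d]", track$origin, i))
  })
}

#' Downsample a track by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass filter (8th-order Butterworth at
#' 80% of the new Nyquist frequency, forward-backward) and decimates. The
#' zero-phase realization avoids shifting event timing. The new rate must
#' stay at or above twice the analysis band edge so wing-beat components
#' remain representable.
#'
#' @param track a `signal_track`.
#' @param factor integer decimation factor (>= 1).
#' @param band_edge_hz upper edge of the analysis band in Hz that the new
#'   rate must support (default 2000).
#' @return a `signal_track` at `fs / factor`.
#' @export
downsample <- function(track, factor, band_edge_hz = 2000) {
  stopifnot(inherits(track, "signal_track"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be a positive integer")
  if (factor == 1L) return(track)
  new_fs <- track$fs / factor
  if (new_fs < 2 * band_edge_hz)
    stop("decimation by ", factor, " yields fs = ", new_fs,
         " < 2 x band edge (", band_edge_hz, " Hz)")
  bt <- signal::butter(8, 0.8 / factor, type = "low")
  y <- signal::filtfilt(bt, track$samples)
  y <- pmin(1, pmax(-1, y))
  signal_track(y[seq.int(1L, length(y), by = factor)], new_fs,
               origin = sprintf("%s[/%d]", track$origin, factor))
}
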