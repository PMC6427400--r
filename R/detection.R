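# Passage-event detection: sliding-window RMS profile compared against a
# threshold. A passage event is a maximal run of windows whose RMS exceeds
# the threshold; the stored event window keeps pad_ms of context on each
# side. Events then pass a standard-group quality filter (minimum core
# duration, direct-passage dip criterion).

#' Detection configuration
#'
#' @param window_ms RMS window length, ms (default 30).
#' @param overlap_ms overlap between consecutive windows, ms (default 10,
#'   i.e. a 20 ms hop at the default window).
#' @param threshold RMS detection threshold (dimensionless), or `"auto"` to
#'   use `auto_k` times the median window RMS of the track.
#' @param auto_k multiplier for the auto threshold (default 5).
#' @param pad_ms context kept on each side of an event, ms (default 50).
#' @param min_duration_ms standard-group core-duration floor, ms (default 100).
#' @param merge_gap_ms maximum sub-threshold gap merged into one event, ms
#'   (default 0: no merging).
#' @param dip_fraction direct-passage criterion: no interior window RMS may
#'   fall below this fraction of the event's peak RMS (default 0.5).
#' @return a `detection_config` list.
#' @export
detection_config <- function(window_ms = 30, overlap_ms = 10,
                             threshold = "auto", auto_k = 5, pad_ms = 50,
                             min_duration_ms = 100, merge_gap_ms = 0,
                             dip_fraction = 0.5) {
  if (overlap_ms <= 0 || overlap_ms >= window_ms)
    stop("need 0 < overlap_ms < window_ms")
  if (is.numeric(threshold) && threshold <= 0) stop("'threshold' must be > 0")
  if (pad_ms < 0) stop("'pad_ms' must be >= 0")
  if (min_duration_ms <= 0) stop("'min_duration_ms' must be > 0")
  structure(list(window_ms = window_ms, overlap_ms = overlap_ms,
                 threshold = threshold, auto_k = auto_k, pad_ms = pad_ms,
                 min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms, dip_fraction = dip_fraction),
            class = "detection_config")
}

#' Sliding-window RMS profile of a track
#'
#' For each window position the value is sqrt(mean(x^2)) over the window;
#' consecutive windows advance by `window_ms - overlap_ms` (20 ms at the
#' defaults). A trailing partial window is dropped.
#'
#' @param track a [signal_track].
#' @param config a [detection_config()].
#' @return an `rms_series`: list with `times` (window-start times, s),
#'   `values` (RMS per window), `window_s`, `hop_s`, `config`.
#' @export
rms_profile <- function(track, config = detection_config()) {
  stopifnot(inherits(track, "signal_track"))
  fs <- track$fs
  n_win <- as.integer(round(config$window_ms / 1000 * fs))
  n_hop <- as.integer(round((config$window_ms - config$overlap_ms) / 1000 * fs))
  if (n_win < 1L || n_hop < 1L) stop("window/hop shorter than one sample")
  n <- length(track$samples)
  if (n < n_win) stop("track shorter than one RMS window")
  starts <- seq.int(1L, n - n_win + 1L, by = n_hop)
  x2 <- track$samples^2
  values <- vapply(starts, function(i) sqrt(sum(x2[i:(i + n_win - 1L)]) / n_win), 0)
  structure(list(times = (starts - 1L) / fs, values = values,
                 window_s = n_win / fs, hop_s = n_hop / fs, config = config),
            class = "rms_series")
}

resolve_threshold <- function(rms, config) {
  if (identical(config$threshold, "auto"))
    config$auto_k * stats::median(rms$values)
  else config$threshold
}

#' Detect passage events from an RMS profile
#'
#' Maximal runs of windows with RMS strictly above the threshold become
#' events. Core bounds run from the start of the first supra-threshold
#' window to the end of the last; runs separated by at most `merge_gap_ms`
#' are merged; padded bounds extend the core by `pad_ms` on each side,
#' clamped to the track. The padded waveform slice is attached to each
#' event.
#'
#' @param rms an `rms_series` computed from `track` with the same config.
#' @param track the source [signal_track].
#' @param config a [detection_config()].
#' @return data.frame of class `event_set`, one row per event: `event_id`,
#'   `core_start_s`, `core_end_s`, `padded_start_s`, `padded_end_s`,
#'   `duration_ms`, `peak_rms`, `standard_group`, `rejection_reason`; the
#'   padded waveform slices are in `attr(, "waveforms")`, and the resolved
#'   threshold in `attr(, "threshold")`.
#' @export
detect_events <- function(rms, track, config = rms$config) {
  stopifnot(inherits(rms, "rms_series"), inherits(track, "signal_track"))
  thr <- resolve_threshold(rms, config)
  above <- rms$values > thr
  ev <- empty_event_set(thr)
  if (!any(above)) return(ev)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts_idx <- ends - r$lengths + 1L
  runs <- data.frame(first = starts_idx[r$values], last = ends[r$values])

  # merge runs separated by short sub-threshold gaps
  if (config$merge_gap_ms > 0 && nrow(runs) > 1L) {
    keep <- runs[1L, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap_s <- rms$times[runs$first[i]] -
        (rms$times[keep$last[nrow(keep)]] + rms$window_s)
      if (gap_s * 1000 <= config$merge_gap_ms) {
        keep$last[nrow(keep)] <- runs$last[i]
      } else {
        keep <- rbind(keep, runs[i, ])
      }
    }
    runs <- keep
  }

  dur_s <- track_duration(track)
  waveforms <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    core_start <- rms$times[runs$first[i]]
    core_end <- rms$times[runs$last[i]] + rms$window_s
    pad_start <- max(0, core_start - config$pad_ms / 1000)
    pad_end <- min(dur_s, core_end + config$pad_ms / 1000)
    i0 <- as.integer(round(pad_start * track$fs)) + 1L
    i1 <- min(length(track$samples), as.integer(round(pad_end * track$fs)))
    waveforms[[i]] <- track$samples[i0:i1]
    ev[i, ] <- list(i, core_start, core_end, pad_start, pad_end,
                    (core_end - core_start) * 1000,
                    max(rms$values[runs$first[i]:runs$last[i]]),
                    NA, "")
  }
  attr(ev, "waveforms") <- waveforms
  attr(ev, "threshold") <- thr
  attr(ev, "run_windows") <- runs
  ev
}

empty_event_set <- function(threshold = NA_real_) {
  ev <- data.frame(event_id = integer(0), core_start_s = numeric(0),
                   core_end_s = numeric(0), padded_start_s = numeric(0),
                   padded_end_s = numeric(0), duration_ms = numeric(0),
                   peak_rms = numeric(0), standard_group = logical(0),
                   rejection_reason = character(0),
                   stringsAsFactors = FALSE)
  attr(ev, "waveforms") <- list()
  attr(ev, "threshold") <- threshold
  class(ev) <- c("event_set", "data.frame")
  ev
}

#' Flag standard-group events
#'
#' An event belongs to the standard group when its core duration (without
#' the added padding) is at least `min_duration_ms` AND it is a direct
#' passage: no interior RMS window of the event falls below `dip_fraction`
#' times the event's peak RMS. The dip rule operationalizes the manual
#' rejection of passages whose signal strength collapses mid-event (the
#' insect did not cross the beam directly); it is this package's proxy for
#' that manual criterion. Rejected events keep a `rejection_reason`
#' ("duration" or "dip").
#'
#' @param events an `event_set` from [detect_events()].
#' @param rms the `rms_series` the events were detected from.
#' @param config a [detection_config()].
#' @return the `event_set` with `standard_group` and `rejection_reason` set.
#' @export
standard_group_filter <- function(events, rms, config = rms$config) {
  stopifnot(inherits(events, "event_set"))
  runs <- attr(events, "run_windows")
  for (i in seq_len(nrow(events))) {
    reasons <- character(0)
    if (events$duration_ms[i] < config$min_duration_ms)
      reasons <- c(reasons, "duration")
    vals <- rms$values[runs$first[i]:runs$last[i]]
    if (length(vals) > 2L) {
      interior <- vals[-c(1L, length(vals))]
      if (any(interior < config$dip_fraction * max(vals)))
        reasons <- c(reasons, "dip")
    }
    events$standard_group[i] <- length(reasons) == 0L
    events$rejection_reason[i] <- paste(reasons, collapse = "+")
  }
  events
}

#' Run detection on a track in one call
#'
#' Convenience wrapper: [rms_profile()], [detect_events()],
#' [standard_group_filter()].
#'
#' @param track a [signal_track].
#' @param config a [detection_config()].
#' @return an `event_set` with standard-group flags set.
#' @export
detect_passages <- function(track, config = detection_config()) {
  rms <- rms_profile(track, config)
  ev <- detect_events(rms, track, config)
  standard_group_filter(ev, rms, config)
}
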