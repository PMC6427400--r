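# Minimal RIFF/PCM WAV I/O, mono 16-bit. Integer full-scale convention:
# int / 32768, so -32768 -> -1.0 and +32767 -> +0.999969.

WAV_FULL_SCALE <- 32768

#' Read a mono PCM WAV file into a signal track
#'
#' Only uncompressed PCM, single-channel files are accepted (the sensor
#' recordings are 16-bit mono). Integer samples are converted to \[-1, 1\]
#' by dividing by the full-scale magnitude of the bit depth (32768 for
#' 16-bit); the sampling rate is taken from the header.
#'
#' @param path path to a WAV file.
#' @return a [signal_track].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, endian = "little"),
        channels     = readBin(body[3:4], "integer", 1L, 2L, endian = "little"),
        fs           = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("no 'fmt ' chunk in ", path)
  if (is.null(data_raw)) stop("no 'data' chunk in ", path)
  if (fmt$audio_format != 1L)
    stop("unsupported encoding (only PCM): format tag ", fmt$audio_format)
  if (fmt$channels != 1L)
    stop("only mono WAV is supported; file has ", fmt$channels, " channels")
  if (fmt$bits != 16L)
    stop("only 16-bit PCM is supported; file has ", fmt$bits, " bits")

  ints <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                  size = 2L, signed = TRUE, endian = "little")
  if (length(ints) == 0L) stop("empty data chunk in ", path)
  signal_track(ints / WAV_FULL_SCALE, fmt$fs, origin = path)
}

#' Write a signal track to a mono PCM WAV file
#'
#' Values are clipped to \[-1, 1\], scaled by the integer full scale and
#' rounded; +1.0 saturates at +32767.
#'
#' @param track a [signal_track].
#' @param path output path.
#' @param bit_depth bits per sample; only 16 is supported.
#' @return `path`, invisibly.
#' @export
write_wav <- function(track, path, bit_depth = 16L) {
  stopifnot(inherits(track, "signal_track"))
  if (!identical(as.integer(bit_depth), 16L))
    stop("only bit_depth = 16 is supported")
  fs <- as.integer(round(track$fs))
  if (is.na(fs) || fs <= 0L) stop("track fs out of range for WAV header")
  x <- pmin(1, pmax(-1, track$samples))
  ints <- as.integer(pmin(WAV_FULL_SCALE - 1, round(x * WAV_FULL_SCALE)))
  n_bytes <- length(ints) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")         # fmt chunk size
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(fs, con, size = 4L, endian = "little")
  writeBin(fs * 2L, con, size = 4L, endian = "little")     # byte rate
  writeBin(2L, con, size = 2L, endian = "little")          # block align
  writeBin(16L, con, size = 2L, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(ints, con, size = 2L, endian = "little")
  invisible(path)
}
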