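#' Construct an audio signal
#'
#' The universal carrier through the pipeline: a finite vector of real
#' amplitudes (nominally in \[-1, 1\], the scale of a normalized PCM WAV)
#' together with its sampling rate.
#'
#' @param samples numeric vector of amplitudes; length >= 2, all finite.
#' @param fs sampling rate in Hz (> 0).
#' @param label free-text description.
#' @return an object of class `audio_signal` with elements `samples`, `fs`
#'   and `label`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 5 * seq(0, 1, by = 1 / 400)), fs = 400)
#' duration(s)
#' @export
audio_signal <- function(samples, fs, label = "") {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop_field("samples", "must be a numeric vector of length >= 2")
  if (!all(is.finite(samples)))
    stop_field("samples", "must be finite throughout")
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 label = as.character(label)[1L]),
            class = "audio_signal")
}

# coerce a bare numeric vector (plus fs) or an audio_signal to audio_signal
as_audio <- function(x, fs = NULL, label = "") {
  if (inherits(x, "audio_signal")) return(x)
  if (is.null(fs)) stop("`fs` is required when `x` is a bare numeric vector")
  audio_signal(x, fs, label)
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$fs, duration(x),
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param x an `audio_signal`.
#' @return duration in seconds.
#' @export
duration <- function(x) length(x$samples) / x$fs

#' Select a time segment of a signal
#'
#' Extracts the half-open sample window `[round(start_s * fs),
#' round(end_s * fs))` (0-based sample arithmetic, so the selected lengths
#' are unambiguous regardless of rounding of the endpoints).
#'
#' @param x an `audio_signal`.
#' @param start_s,end_s segment limits in seconds; `0 <= start_s < end_s <=
#'   duration(x)`.
#' @return an `audio_signal` holding the selected samples.
#' @examples
#' s <- audio_signal(rnorm(4000), fs = 4000)
#' length(select_segment(s, 0.25, 0.75)$samples)  # 2000
#' @export
select_segment <- function(x, start_s, end_s) {
  x <- as_audio(x)
  check_scalar(start_s, "start_s", lower = 0)
  check_scalar(end_s, "end_s", lower = 0)
  if (start_s >= end_s) stop_field("start_s", "must be < end_s")
  if (end_s > duration(x) + 1e-9)
    stop_field("end_s", "must be <= the signal duration")
  i0 <- round(start_s * x$fs)            # 0-based, inclusive
  i1 <- round(end_s * x$fs)              # 0-based, exclusive
  i1 <- min(i1, length(x$samples))
  audio_signal(x$samples[(i0 + 1L):i1], x$fs, x$label)
}

#' Read a mono PCM WAV file
#'
#' Parses a RIFF/WAVE file with integer PCM samples (8, 16, 24 or 32 bit)
#' and returns the samples normalized to \[-1, 1\].  Multichannel files are
#' rejected rather than silently downmixed.
#'
#' @param path path to the WAV file.
#' @param label optional label; defaults to the file name.
#' @return an `audio_signal`.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2L)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      u32 <- function(off) sum(as.numeric(body[off + 1:4]) * 256^(0:3))
      fmt <- list(tag = u16(0L), channels = u16(2L), fs = u32(4L),
                  bits = u16(14L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  if (fmt$tag != 1L)
    stop("unsupported WAV encoding (only integer PCM is read)", call. = FALSE)
  if (fmt$channels != 1L)
    stop("multichannel WAV refused: supply a mono recording", call. = FALSE)
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  samples <- switch(as.character(fmt$bits),
    "8" = (as.numeric(readBin(data_raw, "integer", n, size = 1L,
                              signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", n, size = 2L, signed = TRUE,
                   endian = "little") / 32768,
    "24" = {
      m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
      v <- m[1L, ] + m[2L, ] * 256 + m[3L, ] * 65536
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    },
    "32" = readBin(data_raw, "integer", n, size = 4L,
                   endian = "little") / 2147483648,
    stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE))
  audio_signal(samples, fmt$fs, label)
}

#' Write a signal as 16-bit PCM mono WAV
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16 bits, the canonical
#' dialect for stethoscope exports.
#'
#' @param x an `audio_signal` (or numeric vector with `fs` given).
#' @param path output path.
#' @param fs sampling rate, required when `x` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = NULL) {
  x <- as_audio(x, fs)
  # scale by 32768 to mirror read_wav's normalization (clip the +1 edge)
  q <- as.integer(pmax(-32768L, pmin(32767L,
        round(pmax(-1, pmin(1, x$samples)) * 32768))))
  n <- length(q)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                              endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                              endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + 2L * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(1L); w32(round(x$fs)); w32(round(x$fs) * 2L); w16(2L); w16(16L)
  writeChar("data", con, eos = NULL); w32(2L * n)
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}
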