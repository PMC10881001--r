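#' Construct an AudioTrack
#'
#' A mono sampled waveform with samples in `[-1, 1]`.
#'
#' @param samples Numeric vector of samples; absolute values must not
#'   exceed 1 (within 1e-9 rounding slack).
#' @param sample_rate Sample rate in Hz.
#' @return Object of class `AudioTrack` with `samples`, `sample_rate`,
#'   `duration` (seconds).
#' @export
AudioTrack <- function(samples, sample_rate = 44100) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  if (length(samples) && max(abs(samples)) > 1 + 1e-9)
    stop("samples exceed [-1, 1]; normalize first")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 duration = length(samples) / sample_rate),
            class = "AudioTrack")
}

#' @export
print.AudioTrack <- function(x, ...) {
  cat(sprintf("AudioTrack: %.3f s @ %g Hz (%d samples, peak %.3f)\n",
              x$duration, x$sample_rate, length(x$samples),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Write an AudioTrack to a WAV file
#'
#' Writes a mono RIFF/WAVE file, either 16-bit PCM (default) or 32-bit
#' IEEE float.
#'
#' @param track An [AudioTrack()].
#' @param path Destination `.wav` path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(track, path, bits = 16L) {
  stopifnot(inherits(track, "AudioTrack"), bits %in% c(16L, 32L))
  sr <- as.integer(round(track$sample_rate))
  n <- length(track$samples)
  block_align <- bits %/% 8L           # mono
  data_bytes <- n * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L)
  w16(if (bits == 16L) 1L else 3L)     # 1 = PCM, 3 = IEEE float
  w16(1L)                              # channels
  w32(sr)
  w32(sr * block_align)                # byte rate
  w16(block_align)
  w16(bits)
  writeChar("data", con, eos = NULL)
  w32(data_bytes)
  if (bits == 16L) {
    q <- as.integer(round(pmax(pmin(track$samples, 1), -1) * 32767))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(track$samples, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' Minimal RIFF/WAVE reader for mono PCM-16 and float-32 files; used for
#' round-trip verification.
#'
#' @param path Path to a `.wav` file.
#' @return An [AudioTrack()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4L, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2L, endian = "little")
  tag <- function() readChar(con, 4L, useBytes = TRUE)
  if (tag() != "RIFF") stop("not a RIFF file")
  r32()
  if (tag() != "WAVE") stop("not a WAVE file")
  fmt <- NULL; samples <- NULL
  repeat {
    id <- tag()
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- r32()
    if (id == "fmt ") {
      fmt <- list(code = r16(), channels = r16(), rate = r32(),
                  byte_rate = r32(), block = r16(), bits = r16())
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt")
      if (fmt$bits == 16L) {
        samples <- readBin(con, "integer", n = sz %/% 2L, size = 2L,
                           endian = "little") / 32767
      } else {
        samples <- readBin(con, "double", n = sz %/% 4L, size = 4L,
                           endian = "little")
      }
    } else {
      readBin(con, "raw", sz)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  AudioTrack(pmax(pmin(samples, 1), -1), fmt$rate)
}
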