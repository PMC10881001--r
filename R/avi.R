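#' Write an RGBVideo (with optional audio) to an uncompressed AVI
#'
#' Emits a standard RIFF/AVI container with one uncompressed 24-bit RGB
#' ('DIB ') video stream and, when audio is supplied, one interleaved
#' PCM-16 mono audio stream plus an idx1 index. Uncompressed output keeps
#' frames bit-exact and needs no external encoder.
#'
#' @param video An [RGBVideo()].
#' @param path Destination `.avi` path.
#' @param audio Optional [AudioTrack()] whose duration matches the video.
#' @return `path`, invisibly.
#' @export
write_avi <- function(video, path, audio = NULL) {
  stopifnot(inherits(video, "RGBVideo"))
  d <- dim(video$frames)
  h <- d[1L]; w <- d[2L]; n_t <- d[4L]
  fps <- video$fps
  row_bytes <- w * 3L
  pad <- (4L - row_bytes %% 4L) %% 4L
  frame_bytes <- (row_bytes + pad) * h

  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  fourcc <- function(s) writeChar(s, con, eos = NULL)

  has_audio <- !is.null(audio)
  if (has_audio) {
    stopifnot(inherits(audio, "AudioTrack"))
    sr <- as.integer(round(audio$sample_rate))
    pcm <- as.integer(round(pmax(pmin(audio$samples, 1), -1) * 32767))
    spf <- sr / fps                           # samples per video frame
  }

  # rate as a rational: fps = rate/scale
  scale <- 1000L
  rate <- as.integer(round(fps * scale))

  # pre-encode video frames as raw BGR bottom-up with row padding
  enc_frame <- function(ti) {
    fr <- video$frames[, , , ti]
    q <- array(as.integer(round(fr * 255)), dim(fr))
    rows <- lapply(h:1, function(y) {
      px <- rbind(q[y, , 3L], q[y, , 2L], q[y, , 1L])   # B,G,R per pixel
      c(as.raw(as.vector(px)), raw(pad))
    })
    do.call(c, rows)
  }

  con <- file(path, "wb")
  on.exit(close(con))

  strl_video_size <- 4L + (8L + 56L) + (8L + 40L)
  strl_audio_size <- 4L + (8L + 56L) + (8L + 16L)
  hdrl_size <- 4L + (8L + 56L) + (8L + strl_video_size) +
    if (has_audio) (8L + strl_audio_size) else 0L

  # movi payload sizes
  chunks <- list()
  for (ti in seq_len(n_t)) {
    chunks[[length(chunks) + 1L]] <- list(id = "00db", data = enc_frame(ti))
    if (has_audio) {
      a0 <- floor((ti - 1L) * spf) + 1L
      a1 <- floor(ti * spf)
      seg <- if (a1 >= a0 && a0 <= length(pcm))
        pcm[a0:min(a1, length(pcm))] else integer(0)
      chunks[[length(chunks) + 1L]] <-
        list(id = "01wb", data = writeBin(seg, raw(), size = 2L,
                                          endian = "little"))
    }
  }
  chunk_sizes <- vapply(chunks, function(cch) length(cch$data), integer(1))
  padded <- chunk_sizes + chunk_sizes %% 2L          # RIFF chunks are word-aligned
  movi_size <- 4L + sum(8L + padded)
  idx1_size <- length(chunks) * 16L
  riff_size <- 4L + (8L + hdrl_size) + (8L + movi_size) + (8L + idx1_size)

  fourcc("RIFF"); u32(riff_size); fourcc("AVI ")
  fourcc("LIST"); u32(hdrl_size); fourcc("hdrl")
  # avih
  fourcc("avih"); u32(56L)
  u32(round(1e6 / fps))                              # usec per frame
  u32(frame_bytes * as.integer(ceiling(fps)))        # max bytes/sec (approx)
  u32(0L)                                            # padding granularity
  u32(0x10L + 0x100L)                                # HASINDEX | ISINTERLEAVED
  u32(n_t); u32(0L)
  u32(if (has_audio) 2L else 1L)                     # streams
  u32(frame_bytes); u32(w); u32(h)
  u32(0L); u32(0L); u32(0L); u32(0L)
  # video strl
  fourcc("LIST"); u32(strl_video_size); fourcc("strl")
  fourcc("strh"); u32(56L)
  fourcc("vids"); fourcc("DIB ")
  u32(0L); u16(0L); u16(0L); u32(0L)
  u32(scale); u32(rate)                              # fps = rate/scale
  u32(0L); u32(n_t)                                  # start, length (frames)
  u32(frame_bytes); u32(-1L); u32(0L)                # bufsize, quality, samplesize
  u16(0L); u16(0L); u16(w); u16(h)                   # rcFrame
  fourcc("strf"); u32(40L)
  u32(40L); u32(w); u32(h); u16(1L); u16(24L)
  u32(0L); u32(frame_bytes); u32(0L); u32(0L); u32(0L); u32(0L)
  if (has_audio) {
    block <- 2L
    fourcc("LIST"); u32(strl_audio_size); fourcc("strl")
    fourcc("strh"); u32(56L)
    fourcc("auds"); u32(0L)
    u32(0L); u16(0L); u16(0L); u32(0L)
    u32(1L); u32(sr)                                 # scale=1, rate=sample rate
    u32(0L); u32(length(pcm))                        # length in samples
    u32(sr * block); u32(-1L); u32(block)
    u16(0L); u16(0L); u16(0L); u16(0L)
    fourcc("strf"); u32(16L)
    u16(1L); u16(1L); u32(sr); u32(sr * block); u16(block); u16(16L)
  }
  # movi list with chunk offsets recorded for idx1
  fourcc("LIST"); u32(movi_size); fourcc("movi")
  offsets <- integer(length(chunks))
  off <- 4L                                          # relative to 'movi' fourcc
  for (i in seq_along(chunks)) {
    offsets[i] <- off
    fourcc(chunks[[i]]$id); u32(chunk_sizes[i])
    writeBin(chunks[[i]]$data, con)
    if (chunk_sizes[i] %% 2L) writeBin(raw(1L), con)
    off <- off + 8L + padded[i]
  }
  # idx1
  fourcc("idx1"); u32(idx1_size)
  for (i in seq_along(chunks)) {
    fourcc(chunks[[i]]$id)
    u32(0x10L)                                       # AVIIF_KEYFRAME
    u32(offsets[i]); u32(chunk_sizes[i])
  }
  invisible(path)
}

#' Probe an AVI file's stream metadata
#'
#' Reads the header chunks (avih / strh) and reports per-stream type,
#' length and duration; used to verify audio/video synchronization of
#' muxed output.
#'
#' @param path Path to an `.avi` file.
#' @return List with `width`, `height`, `n_frames`, `fps`, and `streams` --
#'   a data.frame of `type`, `length`, `rate`, `scale`, `duration_s`.
#' @export
read_avi_info <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u32at <- function(p) sum(as.integer(raw[p:(p + 3L)]) * 256^(0:3))
  tag_at <- function(p) rawToChar(raw[p:(p + 3L)])
  if (tag_at(1L) != "RIFF" || tag_at(9L) != "AVI ") stop("not an AVI file")
  streams <- NULL
  width <- height <- n_frames <- NA_integer_; usec <- NA_real_
  pos <- 13L
  scan <- function(pos, end) {
    while (pos + 8L <= end) {
      id <- tag_at(pos); sz <- u32at(pos + 4L)
      body <- pos + 8L
      if (id == "LIST") {
        lt <- tag_at(body)
        if (lt %in% c("hdrl", "strl")) scan(body + 4L, body + sz - 4L)
      } else if (id == "avih") {
        usec <<- u32at(body)
        n_frames <<- u32at(body + 16L)
        width <<- u32at(body + 32L)
        height <<- u32at(body + 36L)
      } else if (id == "strh") {
        type <- tag_at(body)
        scale <- u32at(body + 20L); rate <- u32at(body + 24L)
        len <- u32at(body + 32L)
        streams <<- rbind(streams, data.frame(
          type = type, length = len, rate = rate, scale = scale,
          duration_s = len * scale / rate))
      }
      pos <- body + sz + sz %% 2L
    }
  }
  scan(pos, length(raw))
  list(width = width, height = height, n_frames = n_frames,
       fps = 1e6 / usec, streams = streams)
}

#' Read an uncompressed AVI back into frames and audio
#'
#' Decodes the 24-bit 'DIB ' video chunks and PCM-16 audio chunks of an
#' uncompressed AVI (as produced by [write_avi()]). Used for round-trip
#' verification and by the CLI mux step.
#'
#' @param path Path to an `.avi` file.
#' @return List with `video` (an [RGBVideo()]) and `audio` (an
#'   [AudioTrack()] or `NULL`).
#' @export
read_avi <- function(path) {
  info <- read_avi_info(path)
  raw <- readBin(path, "raw", file.size(path))
  u32at <- function(p) sum(as.integer(raw[p:(p + 3L)]) * 256^(0:3))
  tag_at <- function(p) rawToChar(raw[p:(p + 3L)])
  w <- info$width; h <- info$height
  row_bytes <- w * 3L
  pad <- (4L - row_bytes %% 4L) %% 4L
  # locate the movi list
  pos <- 13L
  movi <- NULL
  while (pos + 8L <= length(raw)) {
    id <- tag_at(pos); sz <- u32at(pos + 4L)
    if (id == "LIST" && tag_at(pos + 8L) == "movi") { movi <- c(pos + 12L, pos + 8L + sz); break }
    pos <- pos + 8L + sz + sz %% 2L
  }
  if (is.null(movi)) stop("no movi list found")
  frames <- list(); pcm <- list()
  pos <- movi[1L]
  while (pos + 8L <= movi[2L]) {
    id <- tag_at(pos); sz <- u32at(pos + 4L)
    body <- pos + 8L
    if (id == "00db") {
      bytes <- as.integer(raw[body:(body + sz - 1L)])
      fr <- array(0, c(h, w, 3L))
      stride <- row_bytes + pad
      for (y in seq_len(h)) {
        row <- bytes[(h - y) * stride + seq_len(row_bytes)]
        px <- matrix(row, nrow = 3L)                  # B,G,R
        fr[y, , 1L] <- px[3L, ]; fr[y, , 2L] <- px[2L, ]; fr[y, , 3L] <- px[1L, ]
      }
      frames[[length(frames) + 1L]] <- fr / 255
    } else if (id == "01wb" && sz > 0L) {
      pcm[[length(pcm) + 1L]] <-
        readBin(raw[body:(body + sz - 1L)], "integer", n = sz %/% 2L,
                size = 2L, endian = "little")
    }
    pos <- body + sz + sz %% 2L
  }
  vid <- RGBVideo(array(unlist(frames), c(h, w, 3L, length(frames))), info$fps)
  aud <- if (length(pcm)) {
    sr <- info$streams$rate[info$streams$type == "auds"][1L]
    AudioTrack(unlist(pcm) / 32767, sr)
  } else NULL
  list(video = vid, audio = aud)
}

#' Mux video and audio into one playable movie file
#'
#' Verifies synchronization first: if the audio is short by less than one
#' frame period it is zero-padded silently; larger mismatches are padded or
#' truncated with a warning. The container is uncompressed AVI (built-in
#' writer); when an `ffmpeg` binary is available on the PATH and `path`
#' ends in `.mp4`, the AVI is transcoded to H.264 MP4. If transcoding
#' fails, the AVI is kept and a message names the fallback.
#'
#' @param video An [RGBVideo()].
#' @param audio An [AudioTrack()].
#' @param path Destination path (`.avi`, or `.mp4` when ffmpeg is present).
#' @return The path actually written, invisibly.
#' @export
mux <- function(video, audio, path) {
  stopifnot(inherits(video, "RGBVideo"), inherits(audio, "AudioTrack"))
  vdur <- n_frames_video(video) / video$fps
  frame_period <- 1 / video$fps
  target_n <- round(vdur * audio$sample_rate)
  diff_s <- audio$duration - vdur
  s <- audio$samples
  if (length(s) < target_n) {
    if (-diff_s > frame_period)
      warning(sprintf("audio %.3f s shorter than video; zero-padding", -diff_s))
    s <- c(s, numeric(target_n - length(s)))
  } else if (length(s) > target_n) {
    if (diff_s > frame_period)
      warning(sprintf("audio %.3f s longer than video; truncating", diff_s))
    s <- s[seq_len(target_n)]
  }
  audio <- AudioTrack(s, audio$sample_rate)
  want_mp4 <- grepl("\\.mp4$", path, ignore.case = TRUE)
  avi_path <- if (want_mp4) sub("\\.mp4$", ".avi", path, ignore.case = TRUE)
              else path
  write_avi(video, avi_path, audio = audio)
  if (want_mp4) {
    ffmpeg <- Sys.which("ffmpeg")
    if (nzchar(ffmpeg)) {
      status <- system2(ffmpeg, c("-y", "-loglevel", "error", "-i",
                                  shQuote(avi_path), "-c:v", "libx264",
                                  "-pix_fmt", "yuv420p", "-c:a", "aac",
                                  shQuote(path)),
                        stdout = FALSE, stderr = FALSE)
      if (status == 0L) { unlink(avi_path); return(invisible(path)) }
      message("ffmpeg transcode failed; keeping uncompressed AVI at ", avi_path)
    } else {
      message("no ffmpeg on PATH; wrote uncompressed AVI at ", avi_path)
    }
    return(invisible(avi_path))
  }
  invisible(path)
}
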