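#' Convert note events to a MIDI track
#'
#' Seconds are the source of truth; ticks are derived as
#' `round(seconds * (tempo_bpm / 60) * ticks_per_beat)`. Overlapping events
#' on the same key are merged into a single note spanning their union (with
#' a warning), since nested note-on/note-off pairs on one key are ambiguous
#' in the MIDI protocol.
#'
#' @param events Note-event data.frame from [component_note_events()] (needs
#'   `onset_s`, `offset_s`, `velocity`, `key`).
#' @param tempo_bpm Tempo in beats per minute (default 120).
#' @param ticks_per_beat MIDI division (default 480).
#' @param channel MIDI channel 0-15 (one per instrument stream).
#' @param program General-MIDI program number 0-127 (0 = acoustic grand
#'   piano, 40 = violin).
#' @param name Track name (meta event).
#' @return Object of class `midi_track`: list with `notes` (data.frame of
#'   `tick_on`, `tick_off`, `key`, `velocity`), `tempo_bpm`,
#'   `ticks_per_beat`, `channel`, `program`, `name`.
#' @export
events_to_midi <- function(events, tempo_bpm = 120, ticks_per_beat = 480L,
                           channel = 0L, program = 0L, name = "sonovis") {
  stopifnot(tempo_bpm > 0, ticks_per_beat >= 1)
  to_tick <- function(s) as.integer(round(s * (tempo_bpm / 60) * ticks_per_beat))
  if (nrow(events)) {
    notes <- data.frame(tick_on = to_tick(events$onset_s),
                        tick_off = to_tick(events$offset_s),
                        key = as.integer(events$key),
                        velocity = as.integer(events$velocity))
    notes$tick_off <- pmax(notes$tick_off, notes$tick_on + 1L)  # nonzero length
    notes <- merge_overlaps(notes)
  } else {
    notes <- data.frame(tick_on = integer(0), tick_off = integer(0),
                        key = integer(0), velocity = integer(0))
  }
  structure(list(notes = notes, tempo_bpm = tempo_bpm,
                 ticks_per_beat = as.integer(ticks_per_beat),
                 channel = as.integer(channel), program = as.integer(program),
                 name = name),
            class = "midi_track")
}

merge_overlaps <- function(notes) {
  out <- NULL
  for (k in unique(notes$key)) {
    nk <- notes[notes$key == k, , drop = FALSE]
    nk <- nk[order(nk$tick_on), , drop = FALSE]
    i <- 1L
    while (i < nrow(nk)) {
      if (nk$tick_on[i + 1L] < nk$tick_off[i]) {
        warning("events_to_midi: overlapping events on key ", k, " merged")
        nk$tick_off[i] <- max(nk$tick_off[i], nk$tick_off[i + 1L])
        nk$velocity[i] <- max(nk$velocity[i], nk$velocity[i + 1L])
        nk <- nk[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
    out <- rbind(out, nk)
  }
  out <- out[order(out$tick_on, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- Standard MIDI File encoding ------------------------------------------

# variable-length quantity encoding (big-endian 7-bit groups)
encode_vlq <- function(x) {
  stopifnot(x >= 0)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0) {                      # higher groups carry the continuation bit
    bytes <- c((x %% 128L) + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

be_bytes <- function(x, n) {
  out <- integer(n)
  for (i in n:1) { out[i] <- x %% 256L; x <- x %/% 256L }
  as.raw(out)
}

#' Write tracks to a Standard MIDI File
#'
#' Format-1 SMF: the first track carries the tempo meta event; each
#' `midi_track` becomes one MTrk chunk with a program change followed by
#' time-sorted note-on/note-off pairs.
#'
#' @param tracks A `midi_track` or list of them (all must share
#'   `ticks_per_beat` and `tempo_bpm`).
#' @param path Destination `.mid` path.
#' @return `path`, invisibly.
#' @export
write_midi <- function(tracks, path) {
  if (inherits(tracks, "midi_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "midi_track")))
  tpb <- tracks[[1L]]$ticks_per_beat
  bpm <- tracks[[1L]]$tempo_bpm
  if (!all(vapply(tracks, function(t) t$ticks_per_beat == tpb &&
                  t$tempo_bpm == bpm, logical(1))))
    stop("all tracks must share ticks_per_beat and tempo_bpm")
  usec_per_beat <- as.integer(round(6e7 / bpm))

  track_chunk <- function(body) {
    c(charToRaw("MTrk"), be_bytes(length(body), 4L), body)
  }
  # conductor track: tempo + end-of-track
  tempo_body <- c(encode_vlq(0L), as.raw(c(0xFF, 0x51, 0x03)),
                  be_bytes(usec_per_beat, 3L),
                  encode_vlq(0L), as.raw(c(0xFF, 0x2F, 0x00)))
  chunks <- list(track_chunk(tempo_body))
  for (tr in tracks) {
    msgs <- track_messages(tr)
    body <- raw(0)
    last <- 0L
    for (i in seq_len(nrow(msgs))) {
      body <- c(body, encode_vlq(msgs$tick[i] - last),
                as.raw(c(msgs$status[i], msgs$d1[i], msgs$d2[i])))
      last <- msgs$tick[i]
    }
    body <- c(as.raw(c(0x00, 0xC0 + tr$channel, tr$program)),  # program change
              body,
              encode_vlq(0L), as.raw(c(0xFF, 0x2F, 0x00)))
    chunks <- c(chunks, list(track_chunk(body)))
  }
  header <- c(charToRaw("MThd"), be_bytes(6L, 4L), be_bytes(1L, 2L),
              be_bytes(length(chunks), 2L), be_bytes(tpb, 2L))
  writeBin(c(header, do.call(c, chunks)), path)
  invisible(path)
}

# flatten a midi_track's notes to time-sorted channel messages
track_messages <- function(tr) {
  n <- nrow(tr$notes)
  if (n == 0L)
    return(data.frame(tick = integer(0), status = integer(0),
                      d1 = integer(0), d2 = integer(0)))
  on <- data.frame(tick = tr$notes$tick_on, status = 0x90 + tr$channel,
                   d1 = tr$notes$key, d2 = tr$notes$velocity, prio = 1L)
  off <- data.frame(tick = tr$notes$tick_off, status = 0x80 + tr$channel,
                    d1 = tr$notes$key, d2 = 0L, prio = 0L)
  msgs <- rbind(on, off)
  msgs <- msgs[order(msgs$tick, msgs$prio, msgs$d1), , drop = FALSE]  # off first
  msgs$prio <- NULL
  rownames(msgs) <- NULL
  msgs
}

#' Parse a Standard MIDI File
#'
#' Byte-level SMF reader, written independently of [write_midi()] and able
#' to parse any format-0/1 file with channel and meta messages (running
#' status supported). Serves as the round-trip oracle for MIDI output.
#'
#' @param path Path to a `.mid` file.
#' @return List: `ticks_per_beat`, `tempo_bpm` (first tempo found, else
#'   120), `tracks` — one data.frame per MTrk with columns `tick_on`,
#'   `tick_off`, `key`, `velocity`, `channel` (note pairs), plus attribute
#'   `program`.
#' @export
read_midi <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u8 <- as.integer(raw)
  pos <- 1L
  rd_u32 <- function() { v <- sum(u8[pos:(pos + 3L)] * 256^(3:0)); pos <<- pos + 4L; v }
  rd_u16 <- function() { v <- u8[pos] * 256L + u8[pos + 1L]; pos <<- pos + 2L; v }
  rd_str <- function(n) { s <- rawToChar(raw[pos:(pos + n - 1L)]); pos <<- pos + n; s }
  if (rd_str(4L) != "MThd") stop("not a MIDI file")
  if (rd_u32() != 6L) stop("bad MThd length")
  fmt <- rd_u16(); ntrk <- rd_u16(); division <- rd_u16()
  if (division >= 32768L) stop("SMPTE time division not supported")
  tempo_bpm <- NULL
  tracks <- list()
  for (k in seq_len(ntrk)) {
    if (rd_str(4L) != "MTrk") stop("expected MTrk chunk")
    len <- rd_u32()
    end <- pos + len
    tick <- 0L
    status <- NA_integer_
    program <- NA_integer_
    active <- list()   # key "<ch>:<key>" -> list(tick, velocity)
    notes <- list()
    while (pos < end) {
      # delta time (VLQ)
      dt <- 0L
      repeat {
        b <- u8[pos]; pos <- pos + 1L
        dt <- dt * 128L + (b %% 128L)
        if (b < 128L) break
      }
      tick <- tick + dt
      b <- u8[pos]
      if (b >= 128L) { status <- b; pos <- pos + 1L } # else running status
      if (status == 255L) {                            # meta
        type <- u8[pos]; pos <- pos + 1L
        mlen <- 0L
        repeat {
          bb <- u8[pos]; pos <- pos + 1L
          mlen <- mlen * 128L + (bb %% 128L)
          if (bb < 128L) break
        }
        if (type == 0x51 && is.null(tempo_bpm)) {
          usec <- sum(u8[pos:(pos + 2L)] * 256^(2:0))
          tempo_bpm <- 6e7 / usec
        }
        pos <- pos + mlen
      } else if (status %in% c(240L, 247L)) {          # sysex
        mlen <- 0L
        repeat {
          bb <- u8[pos]; pos <- pos + 1L
          mlen <- mlen * 128L + (bb %% 128L)
          if (bb < 128L) break
        }
        pos <- pos + mlen
      } else {
        hi <- status %/% 16L
        ch <- status %% 16L
        if (hi %in% c(8L, 9L, 10L, 11L, 14L)) {        # two data bytes
          d1 <- u8[pos]; d2 <- u8[pos + 1L]; pos <- pos + 2L
          if (hi == 9L && d2 > 0L) {
            active[[paste0(ch, ":", d1)]] <- list(tick = tick, velocity = d2)
          } else if (hi == 8L || (hi == 9L && d2 == 0L)) {
            id <- paste0(ch, ":", d1)
            a <- active[[id]]
            if (!is.null(a)) {
              notes[[length(notes) + 1L]] <-
                data.frame(tick_on = a$tick, tick_off = tick, key = d1,
                           velocity = a$velocity, channel = ch)
              active[[id]] <- NULL
            }
          }
        } else {                                       # one data byte
          d1 <- u8[pos]; pos <- pos + 1L
          if (hi == 12L) program <- d1
        }
      }
    }
    df <- if (length(notes)) do.call(rbind, notes)
          else data.frame(tick_on = integer(0), tick_off = integer(0),
                          key = integer(0), velocity = integer(0),
                          channel = integer(0))
    df <- df[order(df$tick_on, df$key), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "program") <- program
    tracks[[k]] <- df
  }
  list(ticks_per_beat = division,
       tempo_bpm = if (is.null(tempo_bpm)) 120 else tempo_bpm,
       tracks = tracks)
}
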