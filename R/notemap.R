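#' Build an ascending chord pitch ladder
#'
#' Generates `n` ascending MIDI keys by cycling through the semitone
#' `intervals` above `root_key`, adding an octave (12 semitones) per cycle.
#' With the default C-minor-7 intervals (C, Eb, G, Bb) and n = 18 the ladder
#' spans 5 octave registers, so nearby components map to consonant,
#' well-separated pitches.
#'
#' @param root_key MIDI key of the root (0-127). Note the octave naming
#'   convention used throughout: key 60 is middle C, written C3.
#' @param intervals Semitone offsets within one octave, each in `[0, 12)`,
#'   e.g. `c(0, 3, 7, 10)` for a minor-seventh chord.
#' @param n Number of keys to emit (>= 1).
#' @return Integer vector of `n` strictly increasing MIDI keys.
#' @examples
#' chord_pitches(36, c(0, 3, 7, 10), 18)  # Cmin7 ladder over 18 components
#' @export
chord_pitches <- function(root_key, intervals = chord_presets$minor7, n) {
  stopifnot(n >= 1, length(intervals) >= 1)
  if (any(intervals < 0) || any(intervals >= 12))
    stop("intervals must lie in [0, 12)")
  if (is.unsorted(intervals, strictly = TRUE))
    stop("intervals must be strictly increasing")
  i <- seq_len(n) - 1L
  keys <- root_key + intervals[(i %% length(intervals)) + 1L] +
    12L * (i %/% length(intervals))
  if (any(keys > 127L))
    stop("pitch ladder exceeds MIDI key 127; choose a lower root_key")
  if (any(keys < 0L)) stop("root_key too low; keys below 0")
  as.integer(keys)
}

#' Chord presets selectable by name
#'
#' Semitone interval sets for common chords/scales: `minor7` (Cmin7-style:
#' root, minor third, fifth, minor seventh), `major` triad, and the major
#' `pentatonic` scale.
#' @export
chord_presets <- list(
  minor7     = c(0L, 3L, 7L, 10L),
  major      = c(0L, 4L, 7L),
  pentatonic = c(0L, 2L, 4L, 7L, 9L)
)

#' Convert a MIDI key to frequency
#'
#' Equal temperament with concert pitch A4 = 440 Hz at key 69:
#' `440 * 2^((key - 69)/12)`.
#'
#' @param key MIDI key (vectorized), each in 0-127.
#' @return Frequency in Hz.
#' @examples
#' midi_to_freq(69)  # 440
#' midi_to_freq(60)  # middle C, ~261.63
#' @export
midi_to_freq <- function(key) {
  if (any(key < 0) || any(key > 127)) stop("MIDI key out of range [0, 127]")
  440 * 2^((key - 69) / 12)
}

#' Pitch names for MIDI keys
#'
#' Converts between MIDI keys and note names under the convention that
#' key 60 is middle C, written C3 (octave = key %/% 12 - 2). Sharps are
#' used for accidentals ("Eb" is accepted on input as "D#").
#'
#' @param key MIDI key (vectorized).
#' @return Character note name, e.g. `"C3"` for key 60.
#' @examples
#' key_name(60)        # "C3"
#' name_to_key("C3")   # 60
#' @export
key_name <- function(key) {
  if (any(key < 0) || any(key > 127)) stop("MIDI key out of range [0, 127]")
  classes <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
  paste0(classes[(key %% 12) + 1L], key %/% 12 - 2L)
}

#' @rdname key_name
#' @param name Note name such as `"C3"`, `"Eb4"`, `"A-1"`.
#' @export
name_to_key <- function(name) {
  classes <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)
  vapply(name, function(nm) {
    m <- regmatches(nm, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)$", nm))[[1L]]
    if (length(m) == 0L) stop("cannot parse note name '", nm, "'")
    pc <- classes[[toupper(m[2L])]] +
      switch(m[3L], "#" = 1L, "b" = -1L, 0L)
    key <- (as.integer(m[4L]) + 2L) * 12L + pc
    if (key < 0L || key > 127L) stop("note '", nm, "' outside the MIDI range")
    key
  }, integer(1), USE.NAMES = FALSE)
}

#' Assign pitches to components via an ordering
#'
#' The component at order position i (i.e. `order[i]`) receives `keys[i]`,
#' so the first-ranked component holds the first (lowest) key. Under
#' first-event ordering this makes notes rise in pitch over time; under
#' centroid ordering pitch tracks anatomical position.
#'
#' @param order Integer permutation: position i holds the component ranked
#'   i-th (as returned by [order_by_centroid()] / [order_by_first_event()]).
#' @param keys MIDI keys, same length as `order`.
#' @return A `pitch_assignment`: data.frame with columns `component`,
#'   `midi_key`, `frequency_hz`, one row per component (sorted by component
#'   id).
#' @export
assign_pitches <- function(order, keys) {
  if (length(order) != length(keys))
    stop("order and keys must have equal length")
  if (!setequal(order, seq_along(order)))
    stop("order must be a permutation of 1..n")
  out <- data.frame(
    component = order,
    midi_key = as.integer(keys),
    frequency_hz = midi_to_freq(keys)
  )
  out <- out[base::order(out$component), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pitch_assignment", "data.frame")
  out
}
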