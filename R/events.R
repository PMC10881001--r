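#' Detect supra-threshold events in a timecourse
#'
#' An event is a maximal run of frames with `h > threshold` whose length is
#' at least `min_len` frames. Onset is the time of the first frame of the
#' run; offset is half-open, the time just after its last frame. The raw
#' strength is the peak amplitude of `h` within the run.
#'
#' @param h Numeric timecourse.
#' @param threshold Event threshold `T`, in signal units (see
#'   [default_threshold()]).
#' @param fps Frame rate (> 0).
#' @param min_len Minimum run length in frames (default 2, suppressing
#'   single-frame noise spikes).
#' @return data.frame with columns `onset_s`, `offset_s`, `strength_raw`,
#'   `onset_frame`, `offset_frame` (1-based, half-open `[onset, offset)`);
#'   zero rows if no event qualifies.
#' @export
detect_events <- function(h, threshold, fps, min_len = 2L) {
  if (fps <= 0) stop("fps must be positive")
  if (min_len < 1L) stop("min_len must be >= 1")
  above <- h > threshold
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty_events())
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    onset_s = (starts - 1L) / fps,
    offset_s = ends / fps,                 # half-open: (last frame + 1)/fps
    strength_raw = vapply(seq_along(starts),
                          function(i) max(h[starts[i]:ends[i]]), numeric(1)),
    onset_frame = starts,
    offset_frame = ends + 1L
  )
}

empty_events <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             strength_raw = numeric(0), onset_frame = integer(0),
             offset_frame = integer(0))
}

#' Default event threshold from a quiescent window
#'
#' `baseline + 2 * SD` computed over the quiescent window (default: frames
#' whose value lies below the component's 25th percentile, a proxy for rest
#' periods). Setting the threshold too low risks fusing several transients
#' into one sustained note, so a conservative multiple of the quiescent
#' spread is used.
#'
#' @param H Timecourse matrix (n x frames) or vector.
#' @param quiescent_frames Optional integer frame indices of a known rest
#'   period; if `NULL`, the sub-25th-percentile frames of each component are
#'   used.
#' @param n_sd SD multiplier (default 2).
#' @return Numeric per-component threshold vector.
#' @export
default_threshold <- function(H, quiescent_frames = NULL, n_sd = 2) {
  if (!is.matrix(H)) H <- matrix(H, nrow = 1L)
  apply(H, 1L, function(h) {
    q <- if (is.null(quiescent_frames)) h[h <= stats::quantile(h, 0.25)]
         else h[quiescent_frames]
    if (length(q) < 2L) q <- h
    mean(q) + n_sd * stats::sd(q)
  })
}

#' Scale raw event strength to MIDI velocity
#'
#' Linear scaling to the 0-127 MIDI velocity range:
#' `round(127 * strength_raw / global_max)`, floored at 1 so every detected
#' event stays audible. A logarithmic option compresses dynamics when weak
#' and strong events span orders of magnitude.
#'
#' @param strength_raw Raw peak amplitudes (vectorized).
#' @param global_max Global maximum amplitude of the dataset (> 0); the
#'   event equal to it encodes to 127.
#' @param log_scale If `TRUE`, scale `log1p(strength)/log1p(global_max)`
#'   instead of linearly.
#' @return Integer velocities in 1..127.
#' @export
scale_strength <- function(strength_raw, global_max, log_scale = FALSE) {
  if (!is.numeric(global_max) || length(global_max) != 1L || global_max <= 0)
    stop("global_max must be a single positive number")
  x <- if (log_scale) log1p(pmax(strength_raw, 0)) / log1p(global_max)
       else strength_raw / global_max
  v <- as.integer(round(127 * pmin(x, 1)))
  pmax(v, 1L)
}

#' Detect and encode note events for all components
#'
#' Runs [detect_events()] per component, scales strengths against the
#' global maximum of `H`, and attaches each component's assigned key.
#'
#' @param H Timecourse matrix (n x frames).
#' @param assignment A [assign_pitches()] result.
#' @param fps Frame rate.
#' @param threshold Per-component threshold vector (recycled if scalar);
#'   default [default_threshold()].
#' @param min_len Minimum event length in frames.
#' @param instrument Instrument class for these events: `"percussive"` or
#'   `"sustained"`.
#' @return data.frame of note events with columns `component`, `onset_s`,
#'   `offset_s`, `strength_raw`, `velocity`, `key`, `instrument`.
#' @export
component_note_events <- function(H, assignment, fps, threshold = NULL,
                                  min_len = 2L,
                                  instrument = c("percussive", "sustained")) {
  instrument <- match.arg(instrument)
  if (!is.matrix(H)) H <- matrix(H, nrow = 1L)
  if (is.null(threshold)) threshold <- default_threshold(H)
  threshold <- rep_len(threshold, nrow(H))
  keys <- assignment$midi_key[match(seq_len(nrow(H)), assignment$component)]
  evs <- lapply(seq_len(nrow(H)), function(j) {
    e <- detect_events(H[j, ], threshold[j], fps, min_len)
    if (nrow(e)) cbind(component = j, e, key = keys[j]) else NULL
  })
  evs <- do.call(rbind, evs)
  if (is.null(evs))
    return(data.frame(component = integer(0), onset_s = numeric(0),
                      offset_s = numeric(0), strength_raw = numeric(0),
                      velocity = integer(0), key = integer(0),
                      instrument = character(0)))
  gmax <- max(H)
  evs$velocity <- scale_strength(evs$strength_raw, gmax)
  evs$instrument <- instrument
  evs[order(evs$onset_s, evs$component),
      c("component", "onset_s", "offset_s", "strength_raw",
        "velocity", "key", "instrument")]
}
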