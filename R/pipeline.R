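#' Build and validate a run configuration
#'
#' Central configuration for the four workflow steps (decompose, render
#' video, sonify, mux). Defaults follow the package's documented choices;
#' everything is overridable. Validation happens here, before any compute.
#'
#' @param input Path to the input movie (TIFF or RDS), or `NULL` when a
#'   built-in fixture is used.
#' @param output_dir Directory for all artifacts (created if needed).
#' @param k Number of components.
#' @param fps Frame rate to attach when the reader needs one.
#' @param ordering `"centroid"` or `"first_event"`.
#' @param order_axis Spatial axis for centroid ordering.
#' @param chord Chord preset name (see [chord_presets]) or an integer
#'   interval vector.
#' @param root_key MIDI key of the chord root (default 36 = C1 in the
#'   C3-is-60 convention).
#' @param audio_mode `"analog"`, `"digital"` or `"both"`.
#' @param instrument Instrument class for the digital stream.
#' @param colormap Color map name for the remix video.
#' @param sample_rate Audio sample rate (Hz).
#' @param filter Apply the active-voxel z-score filter before clustering.
#' @param z_thresh,min_frac Active-voxel filter parameters.
#' @param erode_iter ROI erosion depth.
#' @param seed Integer seed governing all randomness.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = tempfile("sonovis_"),
                       k = 6L, fps = 10, ordering = "centroid",
                       order_axis = 1L, chord = "minor7", root_key = 36L,
                       audio_mode = "both", instrument = "percussive",
                       colormap = "jet", sample_rate = 44100,
                       filter = TRUE, z_thresh = 4, min_frac = 0.05,
                       erode_iter = 1L, seed = 0L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("config error: k must be a positive integer")
  if (!ordering %in% c("centroid", "first_event"))
    stop("config error: ordering must be 'centroid' or 'first_event'")
  if (!audio_mode %in% c("analog", "digital", "both"))
    stop("config error: audio_mode must be analog, digital or both")
  if (!instrument %in% c("percussive", "sustained"))
    stop("config error: unknown instrument class '", instrument, "'")
  if (is.character(chord)) {
    if (!chord %in% names(chord_presets))
      stop("config error: unknown chord preset '", chord, "'")
  } else if (!is.numeric(chord)) {
    stop("config error: chord must be a preset name or interval vector")
  }
  if (!is.null(input) && !file.exists(input))
    stop("config error: input file not found: ", input)
  structure(list(
    input = input, output_dir = output_dir, k = as.integer(k), fps = fps,
    ordering = ordering, order_axis = as.integer(order_axis),
    chord = chord, root_key = as.integer(root_key),
    audio_mode = audio_mode, instrument = instrument, colormap = colormap,
    sample_rate = sample_rate, filter = isTRUE(filter),
    z_thresh = z_thresh, min_frac = min_frac,
    erode_iter = as.integer(erode_iter), seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' CLI flags and explicit arguments override file values.
#'
#' @param path Path to a YAML config file.
#' @param ... Overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the full audiovisualization pipeline
#'
#' Executes the four workflow steps end to end: (1) decompose the movie
#' into W/H components; (2) render the color-remixed component video;
#' (3) sonify the timecourses (analog tones and/or digital MIDI notes);
#' (4) mux the audio with the video into one playable movie. All artifacts
#' plus the resolved config and a stage log are written to
#' `config$output_dir`. Identical config + seed gives identical output.
#'
#' @param config A [run_config()].
#' @param movie Optional pre-loaded [Movie()] (otherwise read from
#'   `config$input`).
#' @return Named list of artifact paths: `decomposition`, `config`, `log`,
#'   `video`, `movie` (muxed), and per-mode `wav_analog` / `wav_digital` /
#'   `midi` entries.
#' @export
run_pipeline <- function(config, movie = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        logf("warning [%s]: %s", name, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    logf("stage %-14s %.2f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  paths <- list()
  # persist the resolved config up front (provenance)
  paths$config <- file.path(config$output_dir, "config.yaml")
  yaml::write_yaml(unclass(config), paths$config)

  if (is.null(movie))
    movie <- stage("read", read_movie(config$input, fps = config$fps))

  decomp <- stage("decompose", decompose_movie(
    movie, k = config$k, seed = config$seed, filter = config$filter,
    z_thresh = config$z_thresh, min_frac = config$min_frac,
    erode_iter = config$erode_iter, ordering = config$ordering,
    order_axis = config$order_axis))
  decomp$colors <- make_colormap(decomp$n, config$colormap, decomp$order)
  paths$decomposition <- file.path(config$output_dir, "decomposition.rds")
  write_decomposition(decomp, paths$decomposition)

  video <- stage("render_video",
                 render_component_video(decomp, C = decomp$colors))
  paths$video <- file.path(config$output_dir, "components.avi")
  stage("write_video", write_avi(video, paths$video))

  intervals <- if (is.character(config$chord)) chord_presets[[config$chord]]
               else as.integer(config$chord)
  keys <- chord_pitches(config$root_key, intervals, decomp$n)
  assignment <- assign_pitches(decomp$order, keys)

  audio <- list()
  if (config$audio_mode %in% c("analog", "both")) {
    a <- stage("sonify_analog", render_analog(
      decomp$H, assignment, fps = decomp$fps,
      sample_rate = config$sample_rate))
    paths$wav_analog <- file.path(config$output_dir, "analog.wav")
    write_wav(a, paths$wav_analog)
    audio$analog <- a
  }
  if (config$audio_mode %in% c("digital", "both")) {
    events <- stage("detect_events", component_note_events(
      decomp$H, assignment, fps = decomp$fps,
      instrument = config$instrument))
    track <- events_to_midi(events,
                            program = if (config$instrument == "sustained") 40L else 0L)
    attr(track, "instrument") <- config$instrument
    paths$midi <- file.path(config$output_dir, "events.mid")
    write_midi(track, paths$midi)
    dig <- stage("render_midi", render_midi_audio(
      track, sample_rate = config$sample_rate,
      duration_s = n_frames(movie) / movie$fps))
    paths$wav_digital <- file.path(config$output_dir, "digital.wav")
    write_wav(dig, paths$wav_digital)
    audio$digital <- dig
  }
  soundtrack <- if (length(audio) == 2L) mix_tracks(audio$analog, audio$digital)
                else audio[[1L]]
  paths$movie <- file.path(config$output_dir, "audiovisualization.avi")
  stage("mux", mux(video, soundtrack, paths$movie))
  logf("done: %d artifacts in %s", length(paths), config$output_dir)
  paths$log <- log_path
  paths
}

#' Self-contained demonstration run
#'
#' Generates a synthetic fixture (6 components, planar) and produces the
#' full dual-stream audiovisualization: the transient "neural" timecourses
#' are encoded as percussive (piano-like) MIDI notes, their slow smoothed
#' "hemodynamic" counterparts as sustained (violin-like) notes, and the
#' analog sinusoid stream is mixed in, so both audio modes and both
#' instrument classes are exercised. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param output_dir Output directory (default a fresh temp dir).
#' @param shape,n_frames,fps Fixture geometry (kept small so the demo runs
#'   in well under two minutes on one CPU).
#' @return Named list of artifact paths: `config`, `decomposition`,
#'   `wav_analog`, `wav_digital`, `midi`, `video`, `movie`, `log`.
#' @export
demo_pipeline <- function(seed = 0L, output_dir = tempfile("sonovis_demo_"),
                          shape = c(32L, 32L), n_frames = 240L, fps = 10) {
  movie <- make_fixture(n = 6, shape = shape, n_frames = n_frames, fps = fps,
                        seed = seed)
  cfg <- run_config(output_dir = output_dir, k = 6L, fps = fps,
                    audio_mode = "both", instrument = "percussive",
                    seed = seed)
  paths <- run_pipeline(cfg, movie = movie)
  # second instrument stream: slow low-passed components as sustained notes
  decomp <- read_decomposition(paths$decomposition)
  H_slow <- t(apply(decomp$H, 1L, smooth_delay, fps = fps, fwhm = 2, delay = 1))
  H_slow[H_slow < 0] <- 0
  keys <- chord_pitches(cfg$root_key, chord_presets[[cfg$chord]], decomp$n)
  assignment <- assign_pitches(decomp$order, keys)
  ev_slow <- component_note_events(H_slow, assignment, fps = fps,
                                   instrument = "sustained")
  tr_slow <- events_to_midi(ev_slow, program = 40L)
  attr(tr_slow, "instrument") <- "sustained"
  ev_fast <- component_note_events(decomp$H, assignment, fps = fps,
                                   instrument = "percussive")
  tr_fast <- events_to_midi(ev_fast, program = 0L)
  attr(tr_fast, "instrument") <- "percussive"
  write_midi(list(tr_fast, tr_slow), paths$midi)
  dig <- render_midi_audio(list(tr_fast, tr_slow),
                           sample_rate = cfg$sample_rate,
                           duration_s = n_frames / fps)
  write_wav(dig, paths$wav_digital)
  soundtrack <- mix_tracks(read_wav(paths$wav_analog), dig)
  video <- render_component_video(decomp, C = decomp$colors)
  mux(video, soundtrack, paths$movie)
  paths
}
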