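#' Upsample a timecourse to an audio-rate amplitude envelope
#'
#' Subtracts the baseline, clips at zero (only signal above baseline is
#' audible) and linearly interpolates from frame rate to sample rate.
#' Linear interpolation avoids the audible "zipper" steps a zero-order hold
#' would produce.
#'
#' @param h Numeric timecourse (one component).
#' @param fps Frame rate of `h` (Hz).
#' @param sample_rate Audio sample rate (Hz).
#' @param baseline Baseline value to subtract (see [default_baseline()]).
#' @return Numeric envelope of length `round(length(h) / fps * sample_rate)`.
#' @export
upsample_envelope <- function(h, fps, sample_rate, baseline = 0) {
  if (fps <= 0 || sample_rate <= 0) stop("fps and sample_rate must be positive")
  env <- pmax(h - baseline, 0)
  n_out <- round(length(h) / fps * sample_rate)
  # frame k covers time [(k-1)/fps, k/fps); sample times at audio rate
  t_frames <- (seq_along(h) - 1) / fps
  t_samps <- (seq_len(n_out) - 1) / sample_rate
  stats::approx(t_frames, env, xout = t_samps, rule = 2L)$y
}

#' Per-component quiescent baseline
#'
#' Default baseline rule: the 10th percentile of each component's
#' timecourse, a robust stand-in for a period of relative quiescence.
#'
#' @param H Timecourse matrix (n x frames) or vector.
#' @param prob Quantile to use (default 0.10).
#' @return Numeric vector of per-component baselines.
#' @export
default_baseline <- function(H, prob = 0.10) {
  if (!is.matrix(H)) H <- matrix(H, nrow = 1L)
  apply(H, 1L, stats::quantile, probs = prob, names = FALSE)
}

#' Render the analog audio stream
#'
#' Each component's timecourse amplitude-modulates a static sinusoid at its
#' assigned pitch; all components play simultaneously and are summed into
#' one waveform, then peak-normalized (default -1 dBFS = 0.891 to leave
#' headroom). Sinusoid phases start at 0, so output is deterministic.
#'
#' @param H Timecourse matrix (n x frames).
#' @param assignment A [assign_pitches()] result covering all components.
#' @param fps Frame rate of H.
#' @param sample_rate Audio sample rate (default 44100 Hz).
#' @param baseline Per-component baseline vector (recycled if scalar);
#'   default from [default_baseline()].
#' @param peak_target Peak amplitude after normalization.
#' @param normalize Set `FALSE` to skip peak normalization (raw linear sum;
#'   used for superposition checks).
#' @return An [AudioTrack()] (or a raw numeric vector if
#'   `normalize = FALSE`).
#' @export
render_analog <- function(H, assignment, fps, sample_rate = 44100,
                          baseline = NULL, peak_target = 0.891,
                          normalize = TRUE) {
  if (!is.matrix(H)) H <- matrix(H, nrow = 1L)
  if (nrow(H) == 0L || ncol(H) == 0L) stop("empty H")
  n <- nrow(H)
  if (!all(seq_len(n) %in% assignment$component))
    stop("assignment does not cover all components")
  if (is.null(baseline)) baseline <- default_baseline(H)
  baseline <- rep_len(baseline, n)
  freqs <- assignment$frequency_hz[match(seq_len(n), assignment$component)]
  if (sample_rate < 2 * max(freqs))
    stop("sample_rate below Nyquist limit for the highest assigned pitch")
  n_samp <- round(ncol(H) / fps * sample_rate)
  tt <- (seq_len(n_samp) - 1) / sample_rate
  mix <- numeric(n_samp)
  for (j in seq_len(n)) {
    env <- upsample_envelope(H[j, ], fps, sample_rate, baseline[j])
    mix <- mix + env * sin(2 * pi * freqs[j] * tt)
  }
  if (!normalize) return(mix)
  AudioTrack(normalize_mix(mix, peak_target), sample_rate)
}

#' Peak-normalize a sample vector
#'
#' Scales so the maximum absolute sample equals `peak_target`. Silence
#' passes through unchanged.
#'
#' @param samples Numeric sample vector (nonempty).
#' @param peak_target Target peak (default 0.891, i.e. -1 dBFS).
#' @return Scaled samples.
#' @export
normalize_mix <- function(samples, peak_target = 0.891) {
  if (length(samples) == 0L) stop("empty sample vector")
  peak <- max(abs(samples))
  if (peak == 0) return(samples)
  samples * (peak_target / peak)
}
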