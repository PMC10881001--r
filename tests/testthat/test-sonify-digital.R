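test_that("event detection implements the threshold/length/strength contract", {
  ev <- detect_events(c(0, 0, 0.5, 0.8, 0.6, 0, 0), threshold = 0.4, fps = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_s, 2)
  expect_equal(ev$offset_s, 5)
  expect_equal(ev$strength_raw, 0.8)

  expect_equal(nrow(detect_events(numeric(10), 0.5, 10)), 0L)

  # threshold splits runs: two one-frame events when min_len allows
  ev2 <- detect_events(c(1, 0, 1), 0.5, fps = 1, min_len = 1L)
  expect_equal(ev2$onset_s, c(0, 2))
  expect_equal(ev2$offset_s, c(1, 3))
  # ...and the default min_len = 2 suppresses them
  expect_equal(nrow(detect_events(c(1, 0, 1), 0.5, fps = 1)), 0L)
})

test_that("event detection agrees with the exhaustive run-scan oracle", {
  set.seed(41)
  for (i in 1:200) {
    fps <- sample(c(5, 10, 30), 1)
    h <- pmax(as.numeric(arima.sim(list(ar = 0.7), 60)), 0)
    thr <- runif(1, 0, 1.5)
    ml <- sample(1:3, 1)
    got <- detect_events(h, thr, fps, ml)
    want <- oracle_events(h, thr, fps, ml)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$onset_s, want$onset_s)
      expect_equal(got$offset_s, want$offset_s)
      expect_equal(got$strength_raw, want$strength_raw)
    }
  }
})

test_that("raising the threshold shrinks events monotonically", {
  # supra-threshold support is nested: frames above a higher threshold are a
  # subset of frames above a lower one, so total event coverage shrinks
  set.seed(42)
  h <- pmax(as.numeric(arima.sim(list(ar = 0.6), 300)), 0)
  frames_at <- function(T) {
    ev <- detect_events(h, T, 10, 1L)
    unlist(lapply(seq_len(nrow(ev)),
                  function(i) ev$onset_frame[i]:(ev$offset_frame[i] - 1L)))
  }
  prev <- frames_at(0)
  for (T in seq(0.2, 2, by = 0.2)) {
    cur <- frames_at(T)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # for isolated unimodal bumps the event count itself is non-increasing
  bump <- dnorm(seq(-3, 3, length.out = 21))
  hb <- c(numeric(5), bump, numeric(5), 2 * bump, numeric(5))
  counts <- vapply(seq(0, 1, by = 0.05),
                   function(T) nrow(detect_events(hb, T, 10, 1L)), integer(1))
  expect_true(all(diff(counts) <= 0))

  # every onset maps back to a frame where h first exceeds the threshold
  ev <- detect_events(h, 0.8, 10, 2L)
  for (i in seq_len(nrow(ev))) {
    fr <- ev$onset_frame[i]
    expect_gt(h[fr], 0.8)
    if (fr > 1) expect_lte(h[fr - 1], 0.8)
  }
})

test_that("strength scaling spans 1..127 with the stated rounding", {
  expect_equal(scale_strength(5, 5), 127L)
  expect_equal(scale_strength(2.5, 5), 64L)      # round(63.5)
  expect_equal(scale_strength(1e-9, 5), 1L)      # floor contract
  expect_error(scale_strength(1, 0), "positive")
  # log option still hits the ceiling at the maximum
  expect_equal(scale_strength(5, 5, log_scale = TRUE), 127L)
})

test_that("MIDI tick conversion and overlap merging follow the contract", {
  ev <- data.frame(onset_s = 0, offset_s = 1, strength_raw = 1,
                   velocity = 100L, key = 60L)
  tr <- events_to_midi(ev, tempo_bpm = 120, ticks_per_beat = 480L)
  expect_equal(tr$notes$tick_on, 0L)
  expect_equal(tr$notes$tick_off - tr$notes$tick_on, 960L)

  empty <- events_to_midi(ev[0, ])
  expect_equal(nrow(empty$notes), 0L)
  f <- tempfile(fileext = ".mid")
  write_midi(empty, f)                            # tempo-only file is valid
  parsed <- read_midi(f)
  expect_equal(parsed$tempo_bpm, 120)
  expect_equal(nrow(parsed$tracks[[2]]), 0L)

  ov <- data.frame(onset_s = c(0, 0.5), offset_s = c(1, 1.5),
                   strength_raw = 1, velocity = c(90L, 100L), key = 60L)
  expect_warning(trm <- events_to_midi(ov), "merged")
  expect_equal(nrow(trm$notes), 1L)
  expect_equal(trm$notes$velocity, 100L)
})

test_that("standard MIDI files round-trip through the independent parser", {
  set.seed(43)
  n <- 40
  on <- sort(runif(n, 0, 30))
  ev <- data.frame(onset_s = on, offset_s = on + runif(n, 0.1, 0.4),
                   strength_raw = 1,
                   velocity = sample(1:127, n, replace = TRUE),
                   key = sample(rep(36:96, 2), n))       # unique keys can repeat
  ev <- ev[order(ev$key, ev$onset_s), ]
  tr <- suppressWarnings(events_to_midi(ev, channel = 0L, program = 0L))
  tr2 <- events_to_midi(data.frame(onset_s = 1, offset_s = 2,
                                   strength_raw = 1, velocity = 64L,
                                   key = 50L),
                        channel = 1L, program = 40L)
  f <- tempfile(fileext = ".mid")
  write_midi(list(tr, tr2), f)
  parsed <- read_midi(f)
  expect_equal(parsed$ticks_per_beat, 480L)
  expect_equal(parsed$tempo_bpm, 120)
  got <- parsed$tracks[[2]]
  want <- tr$notes[order(tr$notes$tick_on, tr$notes$key), ]
  got <- got[order(got$tick_on, got$key), ]
  expect_equal(got$tick_on, want$tick_on)
  expect_equal(got$tick_off, want$tick_off)
  expect_equal(got$key, want$key)
  expect_equal(got$velocity, want$velocity)
  expect_equal(attr(parsed$tracks[[3]], "program"), 40L)
  expect_equal(parsed$tracks[[3]]$channel, 1L)
})

test_that("the built-in synthesizer honors attack, timbre and velocity", {
  mk_track <- function(vel, key = 60L, program = 0L, instrument = NULL) {
    tr <- events_to_midi(data.frame(onset_s = 0.5, offset_s = 1.5,
                                    strength_raw = 1, velocity = vel,
                                    key = key),
                         program = program)
    if (!is.null(instrument)) attr(tr, "instrument") <- instrument
    tr
  }
  sr <- 8000
  out <- render_midi_audio(mk_track(127L), sample_rate = sr)
  onset_idx <- which(abs(out$samples) > 1e-4)[1]
  expect_lt(abs(onset_idx / sr - 0.5), 0.010)     # onset within 10 ms

  # two instrument classes on one key: harmonic magnitude vectors differ
  spec_for <- function(instrument) {
    o <- render_midi_audio(mk_track(127L, instrument = instrument),
                           sample_rate = sr, duration_s = 2)
    seg <- o$samples[round(0.7 * sr):round(1.2 * sr)]
    s <- Mod(fft(seg))[1:(length(seg) / 2)]
    fr <- (seq_along(s) - 1) * sr / length(seg)
    f0 <- midi_to_freq(60)
    vapply(1:5, function(h) max(s[abs(fr - h * f0) < 10]), numeric(1))
  }
  sp_p <- spec_for("percussive"); sp_s <- spec_for("sustained")
  expect_gt(max(abs(sp_p / max(sp_p) - sp_s / max(sp_s))), 0.05)

  silent <- render_midi_audio(mk_track(0L), sample_rate = sr, duration_s = 1)
  expect_true(all(silent$samples == 0))
})

test_that("track mixing is commutative, padding-aware and cancels inverses", {
  set.seed(44)
  a <- AudioTrack(runif(1000, -0.8, 0.8), 8000)
  sil <- AudioTrack(numeric(400), 8000)
  m1 <- mix_tracks(a, sil)
  expect_equal(m1$samples, normalize_mix(a$samples), tolerance = 1e-12)

  neg <- AudioTrack(-a$samples, 8000)
  expect_true(all(mix_tracks(a, neg)$samples == 0))

  b <- AudioTrack(runif(500, -0.5, 0.5), 8000)
  expect_identical(mix_tracks(a, b)$samples, mix_tracks(b, a)$samples)
  expect_error(mix_tracks(a, AudioTrack(numeric(10), 44100)), "rates")
})
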