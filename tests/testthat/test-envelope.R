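test_that("windowed RMS envelope has the analytic value on simple signals", {
  fs <- 48000
  zero <- waveform(rep(0, fs), fs)
  expect_true(all(extract_envelope(zero)$values == 0))
  const <- waveform(rep(0.25, fs / 2), fs)
  e <- extract_envelope(const)
  expect_equal(unique(e$values), 0.25)
  expect_equal(e$rate, 1000)
  # sine of amplitude A with period << window: RMS ~ A / sqrt(2)
  A <- 0.6
  x <- A * sin(2 * pi * 2000 * seq(0, 0.5, by = 1 / fs))
  es <- extract_envelope(waveform(x, fs))
  expect_lt(max(abs(es$values - A / sqrt(2))) / (A / sqrt(2)), 0.01)
})

test_that("envelope extraction validates its inputs", {
  expect_error(waveform(numeric(0), 48000), "empty")
  expect_error(waveform(c(1, NA), 48000), "finite")
  w <- waveform(rnorm(100), 48000) # ~2 ms of audio
  expect_error(extract_envelope(w), "shorter than one analysis window")
  expect_error(extract_envelope(waveform(rnorm(1000), 48000), window_ms = 1,
                                step_ms = 2), "window_ms >= step_ms")
})

test_that("partial final window is dropped, not padded", {
  fs <- 1000 # 10-sample windows, 1-sample steps
  w <- waveform(rep(1, 25), fs)
  e <- extract_envelope(w, window_ms = 10, step_ms = 1)
  expect_length(e$values, 16) # starts 1..16
})

test_that("hp_filter solves the penalized least-squares problem", {
  set.seed(51)
  x <- rnorm(50)
  expect_equal(hp_filter(x, 0), x)
  lin <- 2.5 * (1:80) - 3
  expect_equal(hp_filter(lin, 1e6), lin, tolerance = 1e-8)
  for (lam in c(0.5, 50, 5e4)) {
    expect_equal(hp_filter(x, lam), oracle_hp_dense(x, lam), tolerance = 1e-8)
    expect_lt(abs(mean(hp_filter(x, lam)) - mean(x)), 1e-8)
  }
  expect_error(hp_filter(c(1, NA, 3), 50), "finite")
  expect_error(hp_filter(x, -1), "non-negative")
})

test_that("hp_filter trends smooth monotonically toward a line in lam", {
  set.seed(52)
  x <- cumsum(rnorm(200))
  rough <- function(v) sum(diff(v, differences = 2)^2)
  r <- vapply(c(0, 1, 10, 100, 1e4, 1e6, 1e8), function(l) rough(hp_filter(x, l)),
              numeric(1))
  expect_true(all(diff(r) <= 1e-12))
})

test_that("segment_notes finds nothing in silence and one pulse exactly", {
  silent <- envelope(rep(0, 1000))
  expect_identical(nrow(segment_notes(silent)), 0L)
  v <- rep(0, 1000)
  v[451:550] <- 1 # 100 ms pulse at [450, 550) ms
  notes <- segment_notes(envelope(v))
  expect_identical(nrow(notes), 1L)
  expect_lt(abs(notes$onset_ms - 450), 10)
  expect_lt(abs(notes$offset_ms - 550), 10)
})

test_that("segmentation recovers generator ground truth with >= 30 ms pauses", {
  corp <- gen_song_corpus(song_config(n_songs = 4, deviation = "none", seed = 61))
  for (s in corp$songs) {
    found <- segment_notes(s$envelope)
    expect_identical(nrow(found), nrow(s$notes))
    expect_lt(max(abs(found$onset_ms - s$notes$onset_ms)), 10)
    expect_lt(max(abs(found$offset_ms - s$notes$offset_ms)), 10)
  }
})

test_that("zero_pauses silences pauses, keeps notes, and is idempotent", {
  cfg <- song_config(n_songs = 2, deviation = "none", seed = 71,
                     noise_floor = 0.01)
  s <- gen_song_corpus(cfg)$songs[[1]]
  z <- zero_pauses(s)
  in_note <- rep(FALSE, length(s$envelope$values))
  t_ms <- seq_along(in_note) - 1
  for (i in seq_len(nrow(s$notes))) {
    in_note[t_ms >= s$notes$onset_ms[i] & t_ms < s$notes$offset_ms[i]] <- TRUE
  }
  expect_true(all(z$envelope$values[!in_note] == 0))
  expect_identical(z$envelope$values[in_note], s$envelope$values[in_note])
  expect_identical(zero_pauses(z)$envelope$values, z$envelope$values)
  # notes beyond the envelope are an input error
  bad <- s
  bad$notes$offset_ms[nrow(bad$notes)] <- envelope_duration_ms(s$envelope) + 100
  expect_error(zero_pauses(bad), "within|exceed")
})

test_that("pause zeroing widens the spectrum consistently via small q", {
  # Replacing a 1%-of-peak pause noise floor by exact zeros creates
  # perfectly detrendable windows; the q -> 0 moments are sensitive to them,
  # so the cleaning systematically widens the measured spectrum. The
  # direction is stable across songs, which is why both arms of any study
  # contrast must use the same (zero-pause) treatment.
  corp <- gen_song_corpus(song_config(n_songs = 8, deviation = "mixed",
                                      notes_per_song = c(8, 12),
                                      noise_floor = 0.01, seed = 81))
  w_raw <- vapply(corp$songs, function(s) hurst_spectrum(s$envelope)$width,
                  numeric(1))
  w_zero <- vapply(corp$songs, function(s) {
    hurst_spectrum(zero_pauses(s)$envelope)$width
  }, numeric(1))
  expect_true(all(w_zero > w_raw))
  # at q = 2 alone (no small-q moments) the cleaning is inconsequential
  h_raw <- vapply(corp$songs, function(s) {
    hurst_spectrum(s$envelope, qs = 2)$h
  }, numeric(1))
  h_zero <- vapply(corp$songs, function(s) {
    hurst_spectrum(zero_pauses(s)$envelope, qs = 2)$h
  }, numeric(1))
  expect_lt(max(abs(h_zero - h_raw)), 0.05)
})

test_that("envelope and annotation CSV round-trips preserve content", {
  e <- envelope(abs(sin(1:500 / 30)), rate = 1000, song_id = "rt")
  p <- withr::local_tempfile(fileext = ".csv")
  write_envelope_csv(e, p)
  e2 <- read_envelope_csv(p, song_id = "rt")
  expect_equal(e2$values, e$values)
  expect_equal(e2$rate, 1000)
  notes <- note_annotations(c(0, 200), c(100, 350), c("a", "b"))
  pa <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(notes, "rt", pa)
  back <- read_annotations_csv(pa)
  expect_equal(back$onset_ms, notes$onset_ms)
  expect_equal(back$type_label, notes$type_label)
})

test_that("annotation invariants are enforced", {
  expect_error(note_annotations(10, 5), "onset_ms < offset_ms")
  expect_error(note_annotations(c(0, 50), c(100, 150)), "overlap")
  expect_error(note_annotations(c(50, 0), c(60, 10)), "sorted")
})

test_that("WAV round-trip and stereo downmix work", {
  fs <- 8000
  x <- 0.5 * sin(2 * pi * 440 * seq(0, 0.25, by = 1 / fs))
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(waveform(x, fs, "tone"), p)
  w <- read_wav(p)
  expect_equal(w$sample_rate, fs)
  expect_equal(w$samples, x, tolerance = 1e-4) # 16-bit quantization
  # hand-built stereo file: L = x, R = -x downmixes to ~0
  stereo <- as.vector(rbind(as.integer(round(x * 32767)),
                            as.integer(round(-x * 32767))))
  con <- file(p, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(stereo)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(stereo)), con, size = 4, endian = "little")
  writeBin(stereo, con, size = 2, endian = "little")
  close(con)
  wm <- read_wav(p)
  expect_lt(max(abs(wm$samples)), 1e-4)
})
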