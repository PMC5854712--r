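test_that("collect_instances enumerates exactly the annotated notes", {
  corp <- make_zero_dev_corpus(n_songs = 5)
  inst <- collect_instances(corp)
  expect_length(inst, sum(sapply(corp$songs, function(s) nrow(s$notes))))
  labs <- vapply(inst, `[[`, character(1), "type_label")
  ann_labs <- unlist(lapply(corp$songs, function(s) s$notes$type_label))
  expect_equal(sort(table(labs)), sort(table(ann_labs)), ignore_attr = TRUE)
  expect_length(collect_instances(list()), 0)
  # unlabeled notes are an input error
  bad <- corp$songs[[1]]
  bad$notes$type_label[2] <- NA
  expect_error(collect_instances(list(bad)), "unlabeled")
})

test_that("note profiles average duration and intensity course", {
  mk <- function(dur, height, id) {
    structure(list(song_id = id, type_label = "x", onset_ms = 0,
                   duration_ms = dur, course = rep(height, dur), rate = 1000),
              class = "note_instance")
  }
  prof <- build_note_profiles(list(mk(80, 0.4, "s1"), mk(120, 0.8, "s2")))$x
  expect_equal(prof$mean_duration_ms, 100)
  expect_equal(prof$n_instances, 2)
  expect_true(all(abs(prof$course - 0.6) < 1e-12))
  # identical instances reproduce the instance exactly
  same <- build_note_profiles(list(mk(90, 0.5, "a"), mk(90, 0.5, "b")))$x
  expect_identical(same$course, rep(0.5, 90))
  expect_equal(same$mean_duration_ms, 90)
})

test_that("pause profiles support mean and median statistics", {
  env_of <- function(len) envelope(rep(1, len), rate = 1000)
  mk_song <- function(id, onsets, offsets, labs) {
    song_record(envelope(rep(1, max(offsets)), rate = 1000, song_id = id),
                notes = note_annotations(onsets, offsets, labs),
                provenance = "synthetic")
  }
  s1 <- mk_song("s1", c(0, 120), c(100, 220), c("a", "b"))   # pause 20
  s2 <- mk_song("s2", c(0, 140), c(100, 240), c("a", "b"))   # pause 40
  pp_mean <- build_pause_profiles(list(s1, s2))
  expect_equal(pp_mean$duration_ms, 30)
  expect_equal(pp_mean$n, 2L)
  # pauses a->b: {10, 10, 100} -> median 10, mean 40
  s3 <- mk_song("s3", c(0, 110, 220, 330, 440, 640),
                c(100, 210, 320, 430, 540, 740),
                c("a", "b", "a", "b", "a", "b"))
  pp_med <- build_pause_profiles(list(s3), statistic = "median")
  pp_m <- build_pause_profiles(list(s3), statistic = "mean")
  ab_med <- pp_med$duration_ms[pp_med$left_type == "a" & pp_med$right_type == "b"]
  ab_mean <- pp_m$duration_ms[pp_m$left_type == "a" & pp_m$right_type == "b"]
  expect_equal(ab_med, 10)
  expect_equal(ab_mean, 40)
})

test_that("single pause observations give that duration for either statistic", {
  corp <- make_zero_dev_corpus(n_songs = 1)
  pm <- build_pause_profiles(corp, "mean")
  pmed <- build_pause_profiles(corp, "median")
  key <- function(d) paste(d$left_type, d$right_type)
  pmed <- pmed[match(key(pm), key(pmed)), ]
  single <- pm$n == 1
  expect_true(any(single))
  expect_equal(pm$duration_ms[single], pmed$duration_ms[single])
})

test_that("average-rhythm synthesis reproduces a zero-deviation corpus exactly", {
  corp <- make_zero_dev_corpus(n_songs = 6)
  inst <- collect_instances(corp)
  np <- build_note_profiles(inst)
  pp <- build_pause_profiles(corp)
  for (s in corp$songs) {
    z <- zero_pauses(s)
    avg <- synthesize_average_song(s, np, pp)
    expect_identical(avg$provenance, "average_rhythm")
    expect_equal(avg$envelope$values, z$envelope$values, tolerance = 1e-9)
    expect_identical(avg$notes$type_label, s$notes$type_label)
    expect_equal(avg$notes$onset_ms, s$notes$onset_ms)
  }
})

test_that("synthesized duration is the exact sum of profile durations", {
  corp <- gen_song_corpus(song_config(n_songs = 5, deviation = "jitter", seed = 9))
  np <- build_note_profiles(collect_instances(corp))
  pp <- build_pause_profiles(corp)
  s <- corp$songs[[2]]
  avg <- synthesize_average_song(s, np, pp)
  labs <- s$notes$type_label
  rate <- s$envelope$rate
  expected <- sum(vapply(labs, function(l) {
    round(np[[l]]$mean_duration_ms * rate / 1000)
  }, numeric(1))) +
    sum(vapply(seq_len(length(labs) - 1), function(k) {
      hit <- pp$left_type == labs[k] & pp$right_type == labs[k + 1]
      round(pp$duration_ms[hit][1] * rate / 1000)
    }, numeric(1)))
  expect_equal(length(avg$envelope$values), expected)
})

test_that("missing profiles raise errors naming the offender", {
  corp <- make_zero_dev_corpus(n_songs = 4)
  np <- build_note_profiles(collect_instances(corp))
  pp <- build_pause_profiles(corp)
  s <- corp$songs[[1]]
  np2 <- np[setdiff(names(np), s$notes$type_label[1])]
  expect_error(synthesize_average_song(s, np2, pp), s$notes$type_label[1])
  pp2 <- pp[-(which(pp$left_type == s$notes$type_label[1] &
                      pp$right_type == s$notes$type_label[2])[1]), ]
  expect_error(synthesize_average_song(s, np, pp2), "no pause profile")
})

test_that("deviation series vanish on a zero-deviation corpus", {
  corp <- make_zero_dev_corpus(n_songs = 4)
  np <- build_note_profiles(collect_instances(corp))
  pp <- build_pause_profiles(corp)
  for (s in corp$songs) {
    dv <- deviation_series(s, np, pp)
    expect_true(all(abs(dv$timing$deviation_ms) < 1e-9))
    expect_true(all(abs(dv$intensity$deviation) < 1e-12))
    expect_identical(nrow(dv$timing), nrow(s$notes) - 1L)
    expect_identical(nrow(dv$intensity), nrow(s$notes))
  }
})

test_that("a single late note shows up as its own timing deviation", {
  corp <- make_zero_dev_corpus(n_songs = 4)
  np <- build_note_profiles(collect_instances(corp))
  pp <- build_pause_profiles(corp)
  s <- corp$songs[[2]]
  # delay note 3 by 15 ms: stretch the preceding pause in envelope + notes
  k <- 3
  rate <- s$envelope$rate
  ins_at <- round(s$notes$onset_ms[k] * rate / 1000)
  v <- append(s$envelope$values, rep(0, round(15 * rate / 1000)), after = ins_at)
  notes <- s$notes
  notes$onset_ms[k:nrow(notes)] <- notes$onset_ms[k:nrow(notes)] + 15
  notes$offset_ms[k:nrow(notes)] <- notes$offset_ms[k:nrow(notes)] + 15
  late <- song_record(envelope(v, rate, "late"), notes, provenance = "synthetic")
  dv <- deviation_series(late, np, pp)
  expect_equal(dv$timing$deviation_ms[k - 1], 15)
  expect_true(all(abs(dv$timing$deviation_ms[-(k - 1)]) < 1e-9))
})

test_that("injected tempo drift is recovered with the right slope", {
  cfg <- song_config(n_songs = 12, deviation = "drift", seed = 10)
  corp <- gen_song_corpus(cfg)
  np <- build_note_profiles(collect_instances(corp))
  pp <- build_pause_profiles(corp)
  # pool recovered deviations against ground-truth injected ones
  slope_hat <- numeric(0)
  for (i in seq_along(corp$songs)) {
    dv <- deviation_series(corp$songs[[i]], np, pp)
    k <- dv$timing$transition
    truth_dev <- corp$truth[[i]]$timing_deviation_ms
    fit <- stats::lm(dv$timing$deviation_ms ~ truth_dev)
    slope_hat <- c(slope_hat, unname(stats::coef(fit)[2]))
  }
  # recovered deviations track injected ones 1:1 within 10%
  expect_lt(abs(mean(slope_hat) - 1), 0.1)
})
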