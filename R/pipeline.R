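#' Paired t-test on per-song SD-distances
#'
#' Standard paired-sample t-test on the per-song differences, `df = n - 1`,
#' two-sided p. Used to compare how far original songs and their
#' average-rhythm versions sit above their respective IAAFT surrogate
#' ensembles (in ensemble standard deviations).
#'
#' @param d_orig,d_avg Equal-length numeric vectors (n >= 3), paired by song.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(d_orig, d_avg) {
  if (length(d_orig) != length(d_avg)) stop("inputs must be paired (equal length)")
  n <- length(d_orig)
  if (n < 3) stop("need at least 3 pairs")
  diffs <- d_orig - d_avg
  if (stats::sd(diffs) == 0) stop("degenerate pairing")
  tt <- stats::t.test(d_orig, d_avg, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(diffs))
}

#' Run the full rhythm-expressiveness study on a corpus
#'
#' Orchestrates the whole analysis for every song of a corpus:
#' \enumerate{
#'   \item zero between-note pauses and run MFDFA plus the IAAFT surrogate
#'     test on each original envelope;
#'   \item build per-type note profiles and per-transition pause profiles
#'     from the corpus, re-synthesize each song's average-rhythm version,
#'     and run the same surrogate test on it (with fresh surrogate seeds);
#'   \item compare per-song SD-distances of originals vs. average-rhythm
#'     versions with a paired t-test, for each requested pause statistic
#'     (mean and/or median pause durations).
#' }
#'
#' @param corpus A `song_corpus`, a list of labelled [song_record]s, or a
#'   directory written by [write_corpus()].
#' @param n_surrogates Surrogates per ensemble (study design: 100).
#' @param alpha Significance level for surrogate intervals.
#' @param qs q grid for MFDFA.
#' @param n_scales Number of log-spaced scales.
#' @param pause_stats Character subset of `c("mean", "median")`.
#' @param keep_pause_noise If `TRUE`, additionally analyse the raw (not
#'   pause-zeroed) envelopes and report the paired width difference
#'   (robustness check for the pause-cleaning step).
#' @param max_iter,tol IAAFT stopping parameters (see [iaaft_surrogate()]).
#' @param seed Master seed; per-song and per-stage streams are derived from
#'   it by fixed offsets.
#' @return Object of class `corpus_report`: `songs` (per-song data frame with
#'   widths, interval bounds, SD-distances), `paired` (named list of
#'   [paired_t()] results per pause statistic), `surrogate_widths` (stored
#'   ensembles' widths for re-derivation), `spectra`, settings echo.
#' @export
run_study <- function(corpus, n_surrogates = 100, alpha = 0.05,
                      qs = default_qgrid(), n_scales = 19,
                      pause_stats = c("mean", "median"),
                      keep_pause_noise = FALSE, seed = 1,
                      max_iter = 100, tol = 1e-6) {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  songs <- corpus_songs(corpus)
  n <- length(songs)
  pause_stats <- match.arg(pause_stats, several.ok = TRUE)

  run_version <- function(song, base_seed) {
    e <- song$envelope
    st <- surrogate_test(e, n = n_surrogates, alpha = alpha, qs = qs,
                         scales = log_scales(length(e$values), n_scales = n_scales),
                         seed = base_seed, max_iter = max_iter, tol = tol)
    st
  }

  cleaned <- lapply(songs, function(s) try_stage(zero_pauses, s, "zero_pauses"))
  orig_tests <- lapply(seq_len(n), function(i) {
    try_stage(function(s) run_version(s, seed + i * 1000L),
              cleaned[[i]], paste0("surrogate_test[", songs[[i]]$envelope$song_id, "]"))
  })

  instances <- collect_instances(cleaned)
  note_profiles <- build_note_profiles(instances)

  avg <- list()
  avg_tests <- list()
  for (stat in pause_stats) {
    pp <- build_pause_profiles(cleaned, statistic = stat)
    avg[[stat]] <- lapply(cleaned, function(s) {
      try_stage(function(z) synthesize_average_song(z, note_profiles, pp),
                s, paste0("resynthesis[", s$envelope$song_id, "]"))
    })
    off <- 500000L + 100000L * match(stat, c("mean", "median"))
    avg_tests[[stat]] <- lapply(seq_len(n), function(i) {
      try_stage(function(s) run_version(s, seed + off + i * 1000L),
                avg[[stat]][[i]],
                paste0("surrogate_test_avg_", stat, "[", songs[[i]]$envelope$song_id, "]"))
    })
  }

  per_song <- data.frame(
    song_id = vapply(songs, function(s) s$envelope$song_id, character(1)),
    n_notes = vapply(songs, function(s) nrow(s$notes), integer(1)),
    width_orig = vapply(orig_tests, `[[`, numeric(1), "original_width"),
    ci_low = vapply(orig_tests, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(orig_tests, `[[`, numeric(1), "ci_high"),
    sd_dist_orig = vapply(orig_tests, `[[`, numeric(1), "sd_distance"),
    significant_above = vapply(orig_tests, `[[`, logical(1), "significant_above"),
    stringsAsFactors = FALSE
  )
  paired <- list()
  for (stat in pause_stats) {
    per_song[[paste0("width_avg_", stat)]] <-
      vapply(avg_tests[[stat]], `[[`, numeric(1), "original_width")
    per_song[[paste0("sd_dist_avg_", stat)]] <-
      vapply(avg_tests[[stat]], `[[`, numeric(1), "sd_distance")
    paired[[stat]] <- paired_t(per_song$sd_dist_orig,
                               per_song[[paste0("sd_dist_avg_", stat)]])
  }

  robustness <- NULL
  if (keep_pause_noise) {
    raw_widths <- vapply(songs, function(s) {
      e <- s$envelope
      hurst_spectrum(e, qs = qs,
                     scales = log_scales(length(e$values), n_scales = n_scales))$width
    }, numeric(1))
    d <- per_song$width_orig - raw_widths
    robustness <- list(
      raw_widths = raw_widths,
      mean_width_diff = mean(d),
      t = if (stats::sd(d) > 0) paired_t(per_song$width_orig, raw_widths) else NULL
    )
  }

  structure(list(
    songs = per_song,
    paired = paired,
    surrogate_widths = list(
      orig = lapply(orig_tests, `[[`, "surrogate_widths"),
      avg = lapply(avg_tests, function(v) lapply(v, `[[`, "surrogate_widths"))
    ),
    average_songs = avg,
    robustness = robustness,
    settings = list(n_songs = n, n_surrogates = n_surrogates, alpha = alpha,
                    qs = qs, n_scales = n_scales, pause_stats = pause_stats,
                    seed = seed)
  ), class = "corpus_report")
}

try_stage <- function(f, x, stage) {
  tryCatch(f(x), error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.corpus_report <- function(x, ...) {
  n <- x$settings$n_songs
  cat(sprintf("Corpus report: %d songs, %d surrogates each\n",
              n, x$settings$n_surrogates))
  cat(sprintf("  originals above surrogate interval: %d/%d\n",
              sum(x$songs$significant_above), n))
  for (stat in names(x$paired)) {
    p <- x$paired[[stat]]
    cat(sprintf("  paired t (orig vs avg-rhythm SD-distance, %s pauses): t(%d) = %.2f, p = %.4g\n",
                stat, p$df, p$t, p$p))
  }
  invisible(x)
}

#' Write a corpus to a directory of plain-text files
#'
#' One envelope CSV per song (`<song_id>_env.csv`), a combined annotation CSV
#' (`annotations.csv`), and — for generated corpora — a `truth.json` with the
#' injected ground-truth deviations and a config echo.
#'
#' @param corpus A `song_corpus` or list of [song_record]s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  songs <- corpus_songs(corpus)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- do.call(rbind, lapply(songs, function(s) {
    cbind(song_id = s$envelope$song_id,
          s$notes[, c("onset_ms", "offset_ms", "type_label")])
  }))
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  for (s in songs) {
    write_envelope_csv(s$envelope,
                       file.path(dir, paste0(s$envelope$song_id, "_env.csv")))
  }
  if (inherits(corpus, "song_corpus")) {
    cfg <- corpus$config
    cfg$templates <- lapply(cfg$templates, unclass)
    jsonlite::write_json(
      list(config = unclass(cfg), truth = corpus$truth),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' @param dir Corpus directory.
#' @param provenance Provenance assigned to the loaded songs.
#' @return List of [song_record]s.
#' @export
read_corpus <- function(dir, provenance = "original") {
  ann <- read_annotations_csv(file.path(dir, "annotations.csv"))
  ids <- unique(ann$song_id)
  lapply(ids, function(id) {
    e <- read_envelope_csv(file.path(dir, paste0(id, "_env.csv")), song_id = id)
    notes <- ann[ann$song_id == id, c("onset_ms", "offset_ms", "type_label")]
    rownames(notes) <- NULL
    song_record(e, notes = notes, provenance = provenance)
  })
}

#' Write a corpus report as JSON + CSV tables
#'
#' `report.json` holds the paired tests, settings and stored surrogate
#' widths; `per_song.csv` the per-song widths and SD-distances.
#'
#' @param report A `corpus_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_report <- function(report, dir) {
  stopifnot(inherits(report, "corpus_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$songs, file.path(dir, "per_song.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(paired = report$paired, settings = report$settings,
         surrogate_widths = report$surrogate_widths),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
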