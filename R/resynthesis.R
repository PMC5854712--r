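#' Collect annotated note instances from a corpus
#'
#' Flattens a corpus into one record per annotated note, carrying its
#' envelope slice (the note's amplitude course). Every note must carry a
#' type label.
#'
#' @param corpus A list of [song_record]s, or a `song_corpus` from
#'   [gen_song_corpus()].
#' @return List of `note_instance` records: `song_id`, `type_label`,
#'   `onset_ms`, `duration_ms`, `course`, `rate`.
#' @export
collect_instances <- function(corpus) {
  songs <- corpus_songs(corpus)
  out <- list()
  for (s in songs) {
    e <- s$envelope
    notes <- s$notes
    for (i in seq_len(nrow(notes))) {
      lab <- notes$type_label[i]
      if (is.na(lab) || !nzchar(lab)) {
        stop("unlabeled note at ", notes$onset_ms[i], " ms in song '",
             e$song_id, "'")
      }
      idx <- which(note_mask(e, notes[i, , drop = FALSE]))
      out[[length(out) + 1]] <- structure(list(
        song_id = e$song_id, type_label = lab,
        onset_ms = notes$onset_ms[i],
        duration_ms = notes$offset_ms[i] - notes$onset_ms[i],
        course = e$values[idx], rate = e$rate
      ), class = "note_instance")
    }
  }
  out
}

corpus_songs <- function(corpus) {
  if (inherits(corpus, "song_corpus")) return(corpus$songs)
  if (inherits(corpus, "song_record")) return(list(corpus))
  stopifnot(is.list(corpus), all(vapply(corpus, inherits, TRUE, "song_record")))
  corpus
}

#' Build per-note-type average envelope profiles
#'
#' For each note type, averages duration (arithmetic mean) and intensity
#' course across all instances. Courses of different lengths are made
#' comparable by linear resampling onto a common normalized time grid before
#' pointwise averaging; the grid length defaults to the longest instance
#' course of the type, so that a type whose instances are all identical is
#' reproduced exactly.
#'
#' @param instances List of note instances from [collect_instances()].
#' @param n_grid Normalized-grid length; `NULL` (default) = per type, the
#'   longest instance course.
#' @return Named list of `note_profile` objects: `type_label`,
#'   `mean_duration_ms`, `course` (normalized grid), `n_instances`, `rate`.
#' @export
build_note_profiles <- function(instances, n_grid = NULL) {
  if (length(instances) == 0) stop("no note instances to profile")
  labs <- vapply(instances, `[[`, character(1), "type_label")
  rate <- instances[[1]]$rate
  profiles <- list()
  for (lab in unique(labs)) {
    inst <- instances[labs == lab]
    courses <- lapply(inst, `[[`, "course")
    ng <- if (is.null(n_grid)) max(lengths(courses)) else as.integer(n_grid)
    grid <- seq(0, 1, length.out = ng)
    resampled <- vapply(courses, function(cr) {
      if (length(cr) == 1) rep(cr, ng)
      else stats::approx(seq(0, 1, length.out = length(cr)), cr, xout = grid)$y
    }, numeric(ng))
    profiles[[lab]] <- structure(list(
      type_label = lab,
      mean_duration_ms = mean(vapply(inst, `[[`, numeric(1), "duration_ms")),
      course = rowMeans(resampled),
      n_instances = length(inst), rate = rate
    ), class = "note_profile")
  }
  profiles
}

# Render a note profile at its mean duration and envelope rate.
render_profile <- function(profile, rate = profile$rate) {
  L <- max(1L, as.integer(round(profile$mean_duration_ms * rate / 1000)))
  cr <- profile$course
  if (length(cr) == L) return(cr)
  stats::approx(seq(0, 1, length.out = length(cr)), cr,
                xout = seq(0, 1, length.out = L))$y
}

#' Build per-transition average pause profiles
#'
#' A pause type is identified by its two adjacent note types; for each
#' ordered pair observed in the corpus the pause duration (offset of the left
#' note to onset of the right note) is summarized by the chosen statistic.
#' Medians are offered because pause-duration distributions can be skewed.
#'
#' @param corpus A list of [song_record]s or a `song_corpus`.
#' @param statistic `"mean"` (default) or `"median"`.
#' @return Data frame with columns `left_type`, `right_type`, `duration_ms`,
#'   `statistic`, `n`.
#' @export
build_pause_profiles <- function(corpus, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  songs <- corpus_songs(corpus)
  left <- character(); right <- character(); dur <- numeric()
  for (s in songs) {
    notes <- s$notes
    k <- nrow(notes)
    if (k < 2) next
    left <- c(left, notes$type_label[-k])
    right <- c(right, notes$type_label[-1])
    dur <- c(dur, notes$onset_ms[-1] - notes$offset_ms[-k])
  }
  if (length(dur) == 0) {
    return(data.frame(left_type = character(), right_type = character(),
                      duration_ms = numeric(), statistic = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(left, right, sep = "\r")
  agg <- if (statistic == "mean") tapply(dur, key, mean) else tapply(dur, key, stats::median)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  data.frame(
    left_type = vapply(parts, `[`, character(1), 1),
    right_type = vapply(parts, `[`, character(1), 2),
    duration_ms = as.numeric(agg),
    statistic = statistic,
    n = as.integer(tapply(dur, key, length)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

pause_lookup <- function(pause_profiles, left, right) {
  hit <- pause_profiles$left_type == left & pause_profiles$right_type == right
  if (!any(hit)) {
    stop("no pause profile for transition '", left, "' -> '", right, "'")
  }
  pause_profiles$duration_ms[which(hit)[1]]
}

#' Re-synthesize the "average-rhythm" version of a song
#'
#' Rebuilds the song's envelope from averaged building blocks: each note is
#' replaced by its type's mean-profile course rendered at the type's mean
#' duration, and each pause by the averaged duration of its transition type
#' (zero amplitude), all in the song's original note order. The result keeps
#' the song's syntax but strips every instance-level timing and intensity
#' deviation — the "mechanic" rendition contrasted with the original.
#'
#' @param s The original [song_record] (annotated with type labels).
#' @param note_profiles From [build_note_profiles()].
#' @param pause_profiles From [build_pause_profiles()].
#' @return A [song_record] with provenance `"average_rhythm"` and annotations
#'   at the synthesized onsets/offsets.
#' @export
synthesize_average_song <- function(s, note_profiles, pause_profiles) {
  stopifnot(inherits(s, "song_record"))
  labs <- s$notes$type_label
  if (length(labs) == 0) stop("song has no annotated notes")
  rate <- s$envelope$rate
  missing <- setdiff(labs, names(note_profiles))
  if (length(missing)) {
    stop("no note profile for type(s): ", paste(missing, collapse = ", "))
  }
  courses <- lapply(labs, function(l) render_profile(note_profiles[[l]], rate))
  L <- vapply(courses, length, integer(1))
  K <- length(labs) - 1
  P <- if (K > 0) {
    vapply(seq_len(K), function(k) {
      pause_lookup(pause_profiles, labs[k], labs[k + 1])
    }, numeric(1))
  } else numeric(0)
  Psamp <- as.integer(round(P * rate / 1000))
  pieces <- vector("list", 2 * length(labs) - 1)
  pieces[2 * seq_along(labs) - 1] <- courses
  if (K > 0) pieces[2 * seq_len(K)] <- lapply(Psamp, numeric)
  values <- unlist(pieces, use.names = FALSE)
  ms <- 1000 / rate
  onset_samp <- cumsum(c(0L, (L + c(Psamp, 0L))[-length(labs)]))
  notes <- note_annotations(onset_ms = onset_samp * ms,
                            offset_ms = (onset_samp + L) * ms,
                            type_label = labs)
  song_record(envelope(values, rate = rate,
                       song_id = paste0(s$envelope$song_id, "_avg")),
              notes = notes, provenance = "average_rhythm")
}

#' Per-note timing and intensity deviation series
#'
#' Quantifies how a song deviates from its corpus averages:
#' \describe{
#'   \item{timing}{per transition, the observed onset-to-onset interval minus
#'     the average interval of that transition type (left type's mean
#'     duration + the pair's averaged pause duration), in ms.}
#'   \item{intensity}{per note, the observed mean amplitude minus the mean
#'     amplitude of the type's rendered profile, in envelope units.}
#' }
#' Both are exactly zero for a corpus without instance-level variation.
#'
#' @inheritParams synthesize_average_song
#' @return Object of class `deviation_series`: list with data frames
#'   `timing` (`transition`, `left_type`, `right_type`, `deviation_ms`) and
#'   `intensity` (`note`, `type_label`, `deviation`).
#' @export
deviation_series <- function(s, note_profiles, pause_profiles) {
  stopifnot(inherits(s, "song_record"))
  notes <- s$notes
  labs <- notes$type_label
  n <- length(labs)
  if (n == 0) stop("song has no annotated notes")
  missing <- setdiff(labs, names(note_profiles))
  if (length(missing)) {
    stop("no note profile for type(s): ", paste(missing, collapse = ", "))
  }
  rate <- s$envelope$rate
  prof_mean <- vapply(note_profiles[labs], function(p) {
    mean(render_profile(p, rate))
  }, numeric(1))
  inst <- collect_instances(list(s))
  obs_mean <- vapply(inst, function(x) mean(x$course), numeric(1))
  intensity <- data.frame(note = seq_len(n), type_label = labs,
                          deviation = obs_mean - prof_mean,
                          stringsAsFactors = FALSE)
  if (n > 1) {
    o2o <- notes$onset_ms[-1] - notes$onset_ms[-n]
    expect <- vapply(seq_len(n - 1), function(k) {
      note_profiles[[labs[k]]]$mean_duration_ms +
        pause_lookup(pause_profiles, labs[k], labs[k + 1])
    }, numeric(1))
    timing <- data.frame(transition = seq_len(n - 1),
                         left_type = labs[-n], right_type = labs[-1],
                         deviation_ms = o2o - expect,
                         stringsAsFactors = FALSE)
  } else {
    timing <- data.frame(transition = integer(), left_type = character(),
                         right_type = character(), deviation_ms = numeric(),
                         stringsAsFactors = FALSE)
  }
  structure(list(timing = timing, intensity = intensity,
                 song_id = s$envelope$song_id), class = "deviation_series")
}
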