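#' Waveform container
#'
#' A mono audio waveform: samples (arbitrary units) plus sampling rate.
#'
#' @param samples Finite numeric vector.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param source_id Identifier carried through to derived envelopes.
#' @return Object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate, source_id = "") {
  if (!is.numeric(samples) || length(samples) == 0) stop("empty waveform")
  if (any(!is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a positive number")
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 source_id = as.character(source_id)), class = "waveform")
}

#' Amplitude envelope container
#'
#' The 1000 Hz (by default) non-negative amplitude time series that all
#' analyses in this package consume.
#'
#' @param values Non-negative finite numeric vector.
#' @param rate Envelope sampling rate in Hz.
#' @param song_id Identifier.
#' @return Object of class `envelope`.
#' @export
envelope <- function(values, rate = 1000, song_id = "") {
  if (!is.numeric(values) || length(values) == 0) stop("empty envelope")
  if (any(!is.finite(values))) stop("envelope values must be finite")
  if (any(values < 0)) stop("envelope values must be non-negative")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a positive number")
  }
  structure(list(values = as.numeric(values), rate = as.numeric(rate),
                 song_id = as.character(song_id)), class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("Amplitude envelope '%s': %d samples at %g Hz (%.1f ms)\n",
              x$song_id, length(x$values), x$rate,
              length(x$values) * 1000 / x$rate))
  invisible(x)
}

#' Duration of an envelope in milliseconds
#' @param e An [envelope].
#' @return Scalar duration in ms.
#' @export
envelope_duration_ms <- function(e) length(e$values) * 1000 / e$rate

#' Extract a windowed-RMS amplitude envelope from a waveform
#'
#' Slides a `window_ms` window in `step_ms` steps over the waveform and
#' records the RMS amplitude of each window, yielding an envelope sampled at
#' `1000/step_ms` Hz (1000 Hz for the default 10 ms window / 1 ms step). A
#' partial window at the end of the signal is dropped rather than padded.
#'
#' @param w A [waveform].
#' @param window_ms Window length in ms; must be >= `step_ms`.
#' @param step_ms Hop size in ms; must be > 0.
#' @return An [envelope] at `1000/step_ms` Hz.
#' @export
extract_envelope <- function(w, window_ms = 10, step_ms = 1) {
  stopifnot(inherits(w, "waveform"))
  if (!(step_ms > 0) || window_ms < step_ms) {
    stop("need window_ms >= step_ms > 0")
  }
  fs <- w$sample_rate
  win <- max(1L, as.integer(round(window_ms * fs / 1000)))
  hop <- max(1L, as.integer(round(step_ms * fs / 1000)))
  n <- length(w$samples)
  if (n < win) stop("waveform shorter than one analysis window")
  starts <- seq.int(1L, n - win + 1L, by = hop)
  cs <- c(0, cumsum(w$samples^2))
  vals <- sqrt(pmax(0, (cs[starts + win] - cs[starts]) / win))
  envelope(vals, rate = 1000 / step_ms, song_id = w$source_id)
}

#' Read a mono amplitude envelope from CSV
#'
#' Expects columns `time_ms,amplitude`; the rate is inferred from the median
#' time step.
#'
#' @param path CSV file path.
#' @param song_id Identifier; default the file name without extension.
#' @return An [envelope].
#' @export
read_envelope_csv <- function(path, song_id = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_ms", "amplitude") %in% names(d))) {
    stop("envelope CSV must have columns time_ms, amplitude")
  }
  if (is.null(song_id)) song_id <- sub("\\.[^.]*$", "", basename(path))
  step <- stats::median(diff(d$time_ms))
  envelope(d$amplitude, rate = 1000 / step, song_id = song_id)
}

#' Write an envelope to CSV (`time_ms,amplitude`)
#' @param e An [envelope].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(e, path) {
  stopifnot(inherits(e, "envelope"))
  t_ms <- (seq_along(e$values) - 1) * 1000 / e$rate
  utils::write.csv(data.frame(time_ms = t_ms, amplitude = e$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Note annotation table
#'
#' Builds/validates a note annotation data frame: half-open intervals
#' `[onset_ms, offset_ms)`, 0-based from envelope start, sorted by onset and
#' non-overlapping.
#'
#' @param onset_ms,offset_ms Numeric vectors (ms), `onset_ms < offset_ms`.
#' @param type_label Character vector of note-type labels (may be `NA` before
#'   labelling).
#' @return `data.frame(onset_ms, offset_ms, type_label)`.
#' @export
note_annotations <- function(onset_ms = numeric(), offset_ms = numeric(),
                             type_label = rep(NA_character_, length(onset_ms))) {
  d <- data.frame(onset_ms = as.numeric(onset_ms),
                  offset_ms = as.numeric(offset_ms),
                  type_label = as.character(type_label),
                  stringsAsFactors = FALSE)
  validate_annotations(d)
  d
}

validate_annotations <- function(d) {
  if (nrow(d) == 0) return(invisible(d))
  if (any(d$onset_ms >= d$offset_ms)) stop("every note needs onset_ms < offset_ms")
  if (is.unsorted(d$onset_ms)) stop("notes must be sorted by onset")
  if (nrow(d) > 1 && any(d$onset_ms[-1] < d$offset_ms[-nrow(d)] - 1e-9)) {
    stop("note intervals must not overlap")
  }
  invisible(d)
}

#' Read note annotations from CSV
#'
#' Expects columns `song_id,onset_ms,offset_ms,type_label`.
#'
#' @param path CSV file path.
#' @return A data frame with one row per note, sorted by song and onset.
#' @export
read_annotations_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("song_id", "onset_ms", "offset_ms", "type_label")
  if (!all(need %in% names(d))) {
    stop("annotation CSV must have columns ", paste(need, collapse = ", "))
  }
  d <- d[order(d$song_id, d$onset_ms), need]
  rownames(d) <- NULL
  d
}

#' Write note annotations to CSV
#' @param notes Data frame with `onset_ms`, `offset_ms`, `type_label`.
#' @param song_id Song identifier written into the first column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(notes, song_id, path) {
  utils::write.csv(cbind(song_id = song_id,
                         notes[, c("onset_ms", "offset_ms", "type_label")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Song record: envelope plus ordered note annotations
#'
#' @param envelope An [envelope].
#' @param notes Note annotation data frame (see [note_annotations()]); every
#'   interval must lie within the envelope's duration.
#' @param provenance One of `"original"`, `"average_rhythm"`, `"surrogate"`,
#'   `"synthetic"`.
#' @return Object of class `song_record`.
#' @export
song_record <- function(envelope, notes = note_annotations(),
                        provenance = c("original", "average_rhythm",
                                       "surrogate", "synthetic")) {
  stopifnot(inherits(envelope, "envelope"))
  provenance <- match.arg(provenance)
  validate_annotations(notes)
  dur <- envelope_duration_ms(envelope)
  if (nrow(notes) > 0 &&
      (min(notes$onset_ms) < -1e-9 || max(notes$offset_ms) > dur + 1e-9)) {
    stop("note intervals must lie within [0, ", dur, "] ms")
  }
  structure(list(envelope = envelope, notes = notes, provenance = provenance),
            class = "song_record")
}

#' @export
print.song_record <- function(x, ...) {
  cat(sprintf("Song record '%s' (%s): %d notes, %.0f ms\n",
              x$envelope$song_id, x$provenance, nrow(x$notes),
              envelope_duration_ms(x$envelope)))
  invisible(x)
}
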