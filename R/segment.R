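#' Hodrick-Prescott trend filter
#'
#' Returns the trend \eqn{\tau} minimizing
#' \eqn{\sum_t (x_t - \tau_t)^2 + \lambda \sum_t (\Delta^2 \tau_t)^2},
#' i.e. the solution of the pentadiagonal system
#' \eqn{(I + \lambda D^\top D)\tau = x} with natural (unconstrained)
#' endpoints, solved by a sparse Cholesky factorization. Large `lam` pulls the
#' trend toward a straight line; `lam = 0` returns the input. The difference
#' of a fast (`lam = 50`) and a slow (`lam = 5e7`) trend of an amplitude
#' envelope acts as a band-pass note-onset detector.
#'
#' @param x Finite numeric vector, length >= 3.
#' @param lam Non-negative smoothing coefficient.
#' @return Numeric trend of the same length as `x`.
#' @export
hp_filter <- function(x, lam) {
  x <- as_series(x)
  n <- length(x)
  if (n < 3) stop("hp_filter needs at least 3 observations")
  if (any(!is.finite(x))) stop("hp_filter input must be finite")
  if (!is.finite(lam) || lam < 0) stop("lam must be non-negative")
  if (lam == 0) return(x)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lam * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, x))
}

#' Segment notes from an amplitude envelope
#'
#' Two-stage note detector. Stage 1 finds candidate note regions as maximal
#' runs where the difference between a fast and a slow Hodrick-Prescott trend
#' of the envelope exceeds a threshold (by default 5\% of the difference
#' signal's maximum — the band-passed envelope crossing a small positive
#' level); runs separated by less than `merge_gap_ms` are bridged. Because
#' the zero/threshold crossings of the smoothed difference sit inside the
#' note's quiet attack and decay tails, stage 2 snaps each candidate to the
#' enclosing run of samples whose amplitude exceeds `floor_frac` of the
#' envelope peak (the amplitude floor separating notes from pauses).
#' Candidates shorter than `min_dur_ms` after snapping are discarded. Type
#' labels are left `NA`; they come from annotation files or the synthetic
#' generator.
#'
#' @param e An [envelope] (length >= 3 samples).
#' @param lam_fast,lam_slow HP smoothing coefficients of the two trends.
#' @param min_dur_ms Minimum note duration kept.
#' @param merge_gap_ms Gaps shorter than this are bridged.
#' @param threshold Detection level on the trend difference; `NULL` (default)
#'   uses 5\% of the difference signal's maximum.
#' @param floor_frac Amplitude floor for boundary snapping, as a fraction of
#'   the envelope maximum.
#' @return Note annotation data frame (possibly 0 rows; silence yields none).
#' @export
segment_notes <- function(e, lam_fast = 50, lam_slow = 5e7,
                          min_dur_ms = 5, merge_gap_ms = 3, threshold = NULL,
                          floor_frac = 0.02) {
  stopifnot(inherits(e, "envelope"))
  v <- e$values
  if (length(v) < 3) stop("envelope too short to segment")
  if (max(v) == 0) return(note_annotations())
  d <- hp_filter(v, lam_fast) - hp_filter(v, lam_slow)
  if (is.null(threshold)) threshold <- 0.05 * max(d)
  above <- d > threshold
  if (!any(above)) return(note_annotations())
  runs <- logical_runs(above)
  on <- runs$start
  off <- runs$end # inclusive sample index
  ms <- 1000 / e$rate
  # merge candidates separated by short gaps
  if (length(on) > 1) {
    keep_sep <- (on[-1] - off[-length(off)] - 1L) * ms >= merge_gap_ms
    grp <- cumsum(c(TRUE, keep_sep))
    on <- as.integer(tapply(on, grp, min))
    off <- as.integer(tapply(off, grp, max))
  }
  # snap to the amplitude floor: each candidate expands/contracts to the
  # above-floor runs it intersects
  loud <- logical_runs(v > floor_frac * max(v))
  if (length(loud$start)) {
    for (i in seq_along(on)) {
      hit <- which(loud$start <= off[i] & loud$end >= on[i])
      if (length(hit)) {
        on[i] <- min(loud$start[hit])
        off[i] <- max(loud$end[hit])
      }
    }
    # snapping may merge candidates that landed on the same loud run
    ord <- order(on)
    on <- on[ord]; off <- off[ord]
    if (length(on) > 1) {
      grp <- cumsum(c(TRUE, on[-1] > cummax(off[-length(off)])))
      on <- as.integer(tapply(on, grp, min))
      off <- as.integer(tapply(off, grp, max))
    }
  }
  dur_ok <- (off - on + 1L) * ms >= min_dur_ms
  on <- on[dur_ok]; off <- off[dur_ok]
  note_annotations(onset_ms = (on - 1) * ms, offset_ms = off * ms)
}

# Starts/ends (inclusive, 1-based) of TRUE runs in a logical vector.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(start = starts[r$values], end = ends[r$values])
}

# Logical mask over envelope samples covered by note intervals.
note_mask <- function(e, notes) {
  t_ms <- (seq_along(e$values) - 1) * 1000 / e$rate
  keep <- rep(FALSE, length(t_ms))
  for (i in seq_len(nrow(notes))) {
    keep[t_ms >= notes$onset_ms[i] - 1e-9 & t_ms < notes$offset_ms[i] - 1e-9] <- TRUE
  }
  keep
}

#' Zero the amplitude of between-note pauses
#'
#' Sets envelope samples outside the annotated note intervals to exactly 0 so
#' that recording noise in silent pauses cannot contribute to measured
#' multifractality; samples inside notes are untouched. Idempotent.
#'
#' @param s A [song_record] with non-overlapping notes inside the envelope.
#' @return A new `song_record` with cleaned envelope.
#' @export
zero_pauses <- function(s) {
  stopifnot(inherits(s, "song_record"))
  e <- s$envelope
  if (nrow(s$notes) > 0 &&
      max(s$notes$offset_ms) > envelope_duration_ms(e) + 1e-9) {
    stop("notes exceed envelope duration")
  }
  keep <- note_mask(e, s$notes)
  v <- e$values
  v[!keep] <- 0
  song_record(envelope(v, rate = e$rate, song_id = e$song_id),
              notes = s$notes, provenance = s$provenance)
}
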