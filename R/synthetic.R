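#' Seeded Gaussian white noise
#'
#' @param n Length (>= 16).
#' @param seed Integer seed (RNG state restored on exit).
#' @return Numeric vector of i.i.d. standard normal draws.
#' @export
gen_white_noise <- function(n, seed = 1) {
  if (n < 16) stop("n must be at least 16")
  with_seed(seed, stats::rnorm(n))
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Generates a stationary Gaussian sequence with the exact autocovariance of
#' fractional Gaussian noise at Hurst exponent `H`,
#' \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})/2} (unit variance),
#' via the circulant (Davies-Harte) embedding: the covariance circulant's
#' eigenvalues are obtained by FFT, a complex Gaussian vector is colored by
#' their square roots, and the real part of its FFT has the target
#' covariance. `H = 0.5` reduces to white noise; `H > 0.5` is persistent.
#'
#' @param H Hurst exponent in (0, 1).
#' @param n Length of the output series.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, marginal variance 1.
#' @export
gen_fgn <- function(H, n, seed = 1) {
  if (!is.finite(H) || H <= 0 || H >= 1) stop("H must lie strictly in (0, 1)")
  if (n < 2) stop("n must be at least 2")
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(g[1:(n + 1)], g[n:2])
  m <- length(circ) # 2n
  lam <- Re(stats::fft(circ))
  if (min(lam) < -1e-8 * max(lam)) stop("circulant embedding not nonnegative definite")
  lam <- pmax(lam, 0)
  z <- with_seed(seed, complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)))
  x <- Re(stats::fft(sqrt(lam) * z)) / sqrt(m)
  x[seq_len(n)]
}

#' Binomial multiplicative cascade
#'
#' Builds a length-`2^levels` multifractal reference series by recursively
#' splitting unit mass with weights `(p, 1-p)`, the orientation of each split
#' chosen by a fair seeded coin so the series is stochastic while its scaling
#' exponents are seed-independent with the closed form
#' \eqn{h(q) = 1/q - \log_2(p^q + (1-p)^q)/q}. `p = 0.5` yields a constant
#' series; total mass is conserved exactly at every level.
#'
#' @param p Multiplier weight in (0, 1).
#' @param levels Number of dyadic splits (>= 8; series length `2^levels`).
#' @param seed Integer seed for the split orientations.
#' @return Positive numeric vector of length `2^levels` summing to 1.
#' @export
gen_binomial_cascade <- function(p, levels, seed = 1) {
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  if (levels < 8) stop("need at least 8 cascade levels")
  with_seed(seed, {
    x <- 1
    for (l in seq_len(levels)) {
      flip <- stats::runif(length(x)) < 0.5
      left <- ifelse(flip, p, 1 - p)
      x <- as.vector(rbind(x * left, x * (1 - left)))
    }
    x
  })
}

#' Closed-form generalized Hurst exponent of a binomial cascade
#'
#' @param q Positive moment order(s).
#' @param p Cascade multiplier weight in (0, 1).
#' @return `1/q - log2(p^q + (1-p)^q)/q`, vectorized over `q`.
#' @export
cascade_hq <- function(q, p) {
  1 / q - log2(p^q + (1 - p)^q) / q
}

#' Parametric note envelope template
#'
#' Piecewise-linear attack-sustain-decay amplitude course: linear rise from 0
#' to `peak` over `attack_ms`, hold over `sustain_ms`, linear fall to 0 over
#' `decay_ms`.
#'
#' @param attack_ms,sustain_ms,decay_ms Segment durations in ms (positive).
#' @param peak Peak amplitude (a.u., positive).
#' @return Object of class `note_template`.
#' @export
note_template <- function(attack_ms, sustain_ms, decay_ms, peak = 1) {
  stopifnot(attack_ms > 0, sustain_ms > 0, decay_ms > 0, peak > 0)
  structure(list(attack_ms = attack_ms, sustain_ms = sustain_ms,
                 decay_ms = decay_ms, peak = peak,
                 duration_ms = attack_ms + sustain_ms + decay_ms),
            class = "note_template")
}

#' Default note-type templates
#'
#' Five distinct attack-sustain-decay templates spanning short, loud clicks to
#' long, soft notes (durations 55-170 ms, peaks 0.5-1.0), named `a` to `e`.
#'
#' @param n_types How many of the five defaults to return (recycled with
#'   small duration offsets beyond five).
#' @return Named list of [note_template]s.
#' @export
default_note_templates <- function(n_types = 5) {
  base <- list(
    a = note_template(10, 50, 20, peak = 0.9),
    b = note_template(15, 90, 25, peak = 0.6),
    c = note_template(10, 30, 15, peak = 1.0),
    d = note_template(20, 120, 30, peak = 0.75),
    e = note_template(12, 70, 18, peak = 0.5)
  )
  if (n_types <= 5) return(base[seq_len(n_types)])
  extra <- lapply(seq_len(n_types - 5), function(i) {
    b <- base[[(i - 1) %% 5 + 1]]
    note_template(b$attack_ms, b$sustain_ms + 7 * i, b$decay_ms,
                  peak = min(1, b$peak * 0.9 + 0.05 * i))
  })
  names(extra) <- paste0("t", 5 + seq_along(extra))
  c(base, extra)
}

#' Sample a note template as an envelope course
#'
#' Renders the template at an (optionally time-stretched) duration: the
#' attack/sustain/decay proportions are preserved and the course is sampled
#' at window midpoints, `round(duration_ms * rate / 1000)` samples.
#'
#' @param tpl A [note_template].
#' @param duration_ms Total duration; default the template's own.
#' @param peak_scale Multiplicative amplitude scale.
#' @param rate Envelope rate in Hz.
#' @return Non-negative numeric course.
#' @export
render_template <- function(tpl, duration_ms = NULL, peak_scale = 1, rate = 1000) {
  stopifnot(inherits(tpl, "note_template"))
  if (is.null(duration_ms)) duration_ms <- tpl$duration_ms
  if (duration_ms <= 0) stop("note duration must be positive")
  f <- duration_ms / tpl$duration_ms
  a <- tpl$attack_ms * f
  s <- tpl$sustain_ms * f
  d <- tpl$decay_ms * f
  L <- max(1L, as.integer(round(duration_ms * rate / 1000)))
  t <- (seq_len(L) - 0.5) * duration_ms / L
  shape <- ifelse(t < a, t / a,
                  ifelse(t < a + s, 1, pmax(0, (duration_ms - t) / d)))
  shape * tpl$peak * peak_scale
}

#' Configuration for the synthetic song-corpus generator
#'
#' Defaults mirror the study corpus shape: 24 songs from one singer, 5 note
#' types, 8-20 notes per song, 1000 Hz envelopes, type-dependent base pauses
#' of 40-100 ms. Deviation structure is controlled by `deviation`:
#' \describe{
#'   \item{none}{every note instance of a type is bit-identical.}
#'   \item{jitter}{i.i.d. Gaussian perturbations of note/pause durations
#'     (`jitter_sd_ms`, default 5 ms) and peak amplitudes
#'     (`jitter_amp_frac`, default 5\%).}
#'   \item{drift}{a within-song linear ramp: inter-onset intervals change by
#'     `drift_ms` per transition (accelerando/ritardando analog; ramp
#'     centered in the song so mean tempo is preserved) and peaks ramp
#'     linearly over a `drift_amp_frac` span (crescendo/decrescendo); the
#'     direction of each is drawn per song.}
#'   \item{motif}{a fixed-length timing pattern (`motif_ms` alternating
#'     long-short offsets over `motif_len` transitions) repeats cyclically
#'     through the song.}
#'   \item{mixed}{drift + motif + small jitter (`mixed_jitter_sd_ms`,
#'     `mixed_jitter_amp_frac`).}
#' }
#'
#' @param n_songs Number of songs in the corpus.
#' @param n_types Number of note types.
#' @param templates Named list of [note_template]s; default
#'   [default_note_templates()].
#' @param notes_per_song Integer range `c(min, max)` of notes per song.
#' @param transition Optional row-stochastic first-order transition matrix
#'   over types (rows sum to 1); default uniform (i.i.d. type choice).
#' @param base_pause_ms Optional `n_types x n_types` matrix of pause
#'   durations per ordered type pair; default a fixed type-dependent grid in
#'   [40, 100] ms.
#' @param deviation Deviation mode (see above).
#' @param jitter_sd_ms,jitter_amp_frac Jitter magnitudes.
#' @param drift_ms,drift_amp_frac Drift magnitudes (ms per transition;
#'   total fractional amplitude span).
#' @param motif_len,motif_ms Motif length (transitions) and offset magnitude.
#' @param mixed_jitter_sd_ms,mixed_jitter_amp_frac Jitter magnitudes used in
#'   `mixed` mode.
#' @param noise_floor Uniform noise amplitude added to pause samples
#'   (fraction of 1; 0 = silent pauses), for robustness checks.
#' @param rate Envelope rate in Hz.
#' @param seed Master seed.
#' @return Object of class `song_config`.
#' @export
song_config <- function(n_songs = 24, n_types = 5,
                        templates = default_note_templates(n_types),
                        notes_per_song = c(8, 20),
                        transition = NULL, base_pause_ms = NULL,
                        deviation = c("none", "jitter", "drift", "motif", "mixed"),
                        jitter_sd_ms = 5, jitter_amp_frac = 0.05,
                        drift_ms = 2, drift_amp_frac = 0.2,
                        motif_len = 4, motif_ms = 10,
                        mixed_jitter_sd_ms = 2, mixed_jitter_amp_frac = 0.02,
                        noise_floor = 0, rate = 1000, seed = 1) {
  deviation <- match.arg(deviation)
  stopifnot(n_songs >= 1, n_types >= 1, length(templates) >= n_types,
            notes_per_song[1] >= 2, notes_per_song[2] >= notes_per_song[1],
            rate > 0, noise_floor >= 0)
  if (is.null(transition)) {
    transition <- matrix(1 / n_types, n_types, n_types)
  }
  if (!all(abs(rowSums(transition) - 1) < 1e-9)) {
    stop("transition matrix rows must sum to 1")
  }
  if (is.null(base_pause_ms)) {
    base_pause_ms <- outer(seq_len(n_types), seq_len(n_types),
                           function(i, j) 40 + 10 * ((i + 2 * j) %% 7))
  }
  if (any(base_pause_ms <= 0)) stop("base pauses must be positive")
  structure(list(
    n_songs = n_songs, n_types = n_types,
    templates = templates[seq_len(n_types)],
    notes_per_song = as.integer(notes_per_song),
    transition = transition, base_pause_ms = base_pause_ms,
    deviation = deviation,
    jitter_sd_ms = jitter_sd_ms, jitter_amp_frac = jitter_amp_frac,
    drift_ms = drift_ms, drift_amp_frac = drift_amp_frac,
    motif_len = as.integer(motif_len), motif_ms = motif_ms,
    mixed_jitter_sd_ms = mixed_jitter_sd_ms,
    mixed_jitter_amp_frac = mixed_jitter_amp_frac,
    noise_floor = noise_floor, rate = rate, seed = as.integer(seed)
  ), class = "song_config")
}

#' Generate a synthetic song corpus with known deviation structure
#'
#' Emits `n_songs` [song_record]s built by concatenating note-template
#' envelopes separated by silent pauses, with the deviation structure chosen
#' in the [song_config()] injected on top, and returns the exact ground truth
#' alongside. Songs start at the first note onset and end at the last note
#' offset. Deterministic given the config's seed.
#'
#' @param cfg A [song_config()].
#' @return Object of class `song_corpus`: list with `songs` (list of
#'   [song_record]s, provenance `"synthetic"`), `config`, and `truth` — one
#'   record per song with the type sequence, the injected per-transition
#'   timing deviations (ms, relative to the undisturbed template grid), the
#'   per-note amplitude scale factors, and the undisturbed base onset-to-onset
#'   intervals.
#' @export
gen_song_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "song_config"))
  with_seed(cfg$seed, {
    songs <- vector("list", cfg$n_songs)
    truth <- vector("list", cfg$n_songs)
    for (i in seq_len(cfg$n_songs)) {
      g <- gen_one_song(cfg, song_id = sprintf("syn%02d", i))
      songs[[i]] <- g$song
      truth[[i]] <- g$truth
    }
    structure(list(songs = songs, config = cfg, truth = truth),
              class = "song_corpus")
  })
}

# Draw a type sequence from the first-order transition model.
draw_type_sequence <- function(cfg, n_notes) {
  types <- integer(n_notes)
  types[1] <- sample.int(cfg$n_types, 1)
  for (k in seq_len(n_notes - 1)) {
    types[k + 1] <- sample.int(cfg$n_types, 1, prob = cfg$transition[types[k], ])
  }
  types
}

gen_one_song <- function(cfg, song_id) {
  n_notes <- sample(seq(cfg$notes_per_song[1], cfg$notes_per_song[2]), 1)
  types <- draw_type_sequence(cfg, n_notes)
  labels <- names(cfg$templates)[types]
  base_dur <- vapply(cfg$templates[types], function(t) t$duration_ms, numeric(1))
  base_pause <- if (n_notes > 1) {
    cfg$base_pause_ms[cbind(types[-n_notes], types[-1])]
  } else numeric(0)

  K <- n_notes - 1 # transitions
  dur_dev <- numeric(n_notes)
  pause_dev <- numeric(max(K, 0))
  amp_scale <- rep(1, n_notes)
  mode <- cfg$deviation
  if (mode %in% c("jitter", "mixed")) {
    sd_ms <- if (mode == "jitter") cfg$jitter_sd_ms else cfg$mixed_jitter_sd_ms
    sd_amp <- if (mode == "jitter") cfg$jitter_amp_frac else cfg$mixed_jitter_amp_frac
    dur_dev <- dur_dev + stats::rnorm(n_notes, 0, sd_ms)
    if (K > 0) pause_dev <- pause_dev + stats::rnorm(K, 0, sd_ms)
    amp_scale <- amp_scale * (1 + stats::rnorm(n_notes, 0, sd_amp))
  }
  if (mode %in% c("drift", "mixed") && K > 0) {
    tempo_sign <- sample(c(-1, 1), 1)
    amp_sign <- sample(c(-1, 1), 1)
    k <- seq_len(K)
    pause_dev <- pause_dev + tempo_sign * cfg$drift_ms * (k - (K + 1) / 2)
    ramp <- (seq_len(n_notes) - 1) / max(n_notes - 1, 1) - 0.5
    amp_scale <- amp_scale * (1 + amp_sign * cfg$drift_amp_frac * ramp)
  }
  if (mode %in% c("motif", "mixed") && K > 0) {
    pat <- cfg$motif_ms * rep_len(c(1, -1, 0.5, -0.5), cfg$motif_len)
    pause_dev <- pause_dev + rep_len(pat, K)
  }

  dur <- base_dur + dur_dev
  pause <- base_pause + pause_dev
  if (any(dur <= 0)) stop("deviation magnitudes produced a non-positive note duration")
  if (any(pause <= 0)) stop("deviation magnitudes produced a non-positive pause")
  if (any(amp_scale <= 0)) stop("deviation magnitudes produced a non-positive amplitude")

  courses <- lapply(seq_len(n_notes), function(j) {
    render_template(cfg$templates[[types[j]]], duration_ms = dur[j],
                    peak_scale = amp_scale[j], rate = cfg$rate)
  })
  L <- vapply(courses, length, integer(1))
  P <- as.integer(round(pause * cfg$rate / 1000))

  pieces <- vector("list", 2 * n_notes - 1)
  pieces[2 * seq_len(n_notes) - 1] <- courses
  if (K > 0) pieces[2 * seq_len(K)] <- lapply(P, numeric)
  values <- unlist(pieces, use.names = FALSE)

  onset_samp <- cumsum(c(0L, (L + c(P, 0L))[-n_notes]))
  ms <- 1000 / cfg$rate
  notes <- note_annotations(onset_ms = onset_samp * ms,
                            offset_ms = (onset_samp + L) * ms,
                            type_label = labels)
  if (cfg$noise_floor > 0) {
    env_tmp <- envelope(values, rate = cfg$rate, song_id = song_id)
    in_note <- note_mask(env_tmp, notes)
    values[!in_note] <- stats::runif(sum(!in_note), 0, cfg$noise_floor)
  }
  song <- song_record(envelope(values, rate = cfg$rate, song_id = song_id),
                      notes = notes, provenance = "synthetic")
  truth <- list(
    song_id = song_id, types = labels,
    base_duration_ms = base_dur, duration_ms = dur,
    base_pause_ms = base_pause, pause_ms = pause,
    base_o2o_ms = if (K > 0) base_dur[-n_notes] + base_pause else numeric(0),
    timing_deviation_ms = if (K > 0) dur_dev[-n_notes] + pause_dev else numeric(0),
    amp_scale = amp_scale
  )
  list(song = song, truth = truth)
}
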