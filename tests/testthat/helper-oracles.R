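# Independent brute-force oracles, deliberately written in the most naive way
# possible so they share no code path with the package internals.

# Dense direct solve of the HP-filter normal equations.
oracle_hp_dense <- function(x, lam) {
  n <- length(x)
  D <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  solve(diag(n) + lam * t(D) %*% D, x)
}

# Per-window mean-square residuals via lm(), both-ends windowing.
oracle_window_f2 <- function(Y, s) {
  n <- length(Y)
  m <- n %/% s
  f2 <- numeric(0)
  for (v in seq_len(m)) {
    w <- Y[((v - 1) * s + 1):(v * s)]
    f2 <- c(f2, mean(stats::resid(stats::lm(w ~ seq_len(s)))^2))
  }
  for (v in seq_len(m)) {
    w <- Y[(n - v * s + 1):(n - (v - 1) * s)]
    f2 <- c(f2, mean(stats::resid(stats::lm(w ~ seq_len(s)))^2))
  }
  f2
}

# Naive q-order fluctuation from scratch (integration included).
oracle_fq <- function(x, s, q) {
  Y <- numeric(length(x))
  acc <- 0
  for (i in seq_along(x)) {
    acc <- acc + (x[i] - mean(x))
    Y[i] <- acc
  }
  f2 <- oracle_window_f2(Y, s)
  (mean(f2^(q / 2)))^(1 / q)
}

# Naive IAAFT for cross-checking the compiled loop on small inputs.
oracle_iaaft <- function(x, r0, max_iter = 100, tol = 1e-6) {
  n <- length(x)
  amp <- Mod(stats::fft(x))
  amp_norm <- sqrt(sum(amp^2))
  sorted_x <- sort(x)
  r <- r0
  best <- r
  best_disc <- Inf
  for (it in seq_len(max_iter)) {
    f <- stats::fft(r)
    mod <- Mod(f)
    mod[mod == 0] <- 1
    cand <- Re(stats::fft(f * (amp / mod), inverse = TRUE)) / n
    r <- sorted_x[rank(cand, ties.method = "first")]
    disc <- sqrt(sum((Mod(stats::fft(r)) - amp)^2)) / amp_norm
    if (disc >= best_disc) break
    improved <- best_disc - disc
    best <- r
    best_disc <- disc
    if (is.finite(improved) && improved < tol) break
  }
  best
}

# Relative L2 discrepancy between amplitude spectra.
spectral_error <- function(a, b) {
  fa <- Mod(stats::fft(a))
  fb <- Mod(stats::fft(b))
  sqrt(sum((fa - fb)^2)) / sqrt(sum(fa^2))
}

# Small fully-deterministic labelled corpus for resynthesis tests.
make_zero_dev_corpus <- function(n_songs = 6, seed = 7, ...) {
  gen_song_corpus(song_config(n_songs = n_songs, deviation = "none",
                              seed = seed, ...))
}
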