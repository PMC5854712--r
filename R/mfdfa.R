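#' Integrate a series into a random-walk profile
#'
#' Converts a series into its cumulative mean-centered profile
#' \eqn{Y(i) = \sum_{k \le i} (x_k - \bar x)}, the "random-walk" form on which
#' detrended fluctuation analysis operates. The last element is zero up to
#' rounding error (telescoping sum).
#'
#' @param x Numeric vector, length >= 2, finite, or an [envelope].
#' @return Numeric vector of the same length as `x`.
#' @seealso [hurst_spectrum()]
#' @export
#' @examples
#' integrate_profile(c(1, 2, 3)) # -1 -1 0
integrate_profile <- function(x) {
  x <- as_series(x)
  if (length(x) < 2) stop("need at least 2 observations to build a profile")
  cumsum(x - mean(x))
}

#' Logarithmically spaced window sizes for fluctuation analysis
#'
#' Builds the default scale grid: `n_scales` log-spaced integer window lengths
#' spanning `[s_min, s_max]`, deduplicated after rounding. Defaults follow the
#' usual DFA convention of scales between 10 samples and a quarter of the
#' series length, so every scale admits at least 4 non-overlapping windows.
#'
#' @param n Series length (positive integer).
#' @param n_scales Number of grid points before deduplication.
#' @param s_min Smallest window length in samples.
#' @param s_max Largest window length; default `floor(n/4)`.
#' @return Strictly increasing integer vector of window lengths.
#' @export
log_scales <- function(n, n_scales = 19, s_min = 10, s_max = floor(n / 4)) {
  if (s_max < s_min) {
    stop("series too short for fluctuation analysis: need length >= ", 4 * s_min)
  }
  raw <- exp(seq(log(s_min), log(s_max), length.out = n_scales))
  unique(as.integer(round(raw)))
}

#' Default q-grid for multifractal analysis
#'
#' Strictly positive, strictly increasing moment orders from `q_min` to
#' `q_max` in steps of `q_step`. The defaults (0.1 to 5.0 by 0.1) weight both
#' small-fluctuation (`q < 2`) and large-fluctuation (`q > 2`) windows.
#'
#' @param q_min,q_max,q_step Grid limits and spacing; all must yield q > 0.
#' @return Numeric vector of q values.
#' @export
default_qgrid <- function(q_min = 0.1, q_max = 5, q_step = 0.1) {
  q <- seq(q_min, q_max, by = q_step)
  check_qgrid(q)
  q
}

check_qgrid <- function(q) {
  if (length(q) < 1 || any(!is.finite(q)) || any(q <= 0)) {
    stop("q grid must contain finite, strictly positive values")
  }
  if (is.unsorted(q, strictly = TRUE)) stop("q grid must be strictly increasing")
  invisible(q)
}

#' Per-window mean-square residuals of a profile at one scale
#'
#' Partitions the profile into `floor(N/s)` non-overlapping windows of length
#' `s` from the start and, because the tail would otherwise be discarded when
#' `N` is not a multiple of `s`, the same number again counted from the end
#' (both-ends convention, `2*floor(N/s)` windows in total). Each window gets
#' an ordinary least-squares line fit; the mean of squared residuals per
#' window is returned.
#'
#' @param Y Profile series (see [integrate_profile()]).
#' @param s Window length in samples, `10 <= s <= length(Y)/4`.
#' @return Numeric vector of length `2*floor(length(Y)/s)`, all entries >= 0.
#'   Forward-pass windows come first, then the backward pass.
#' @export
windowed_residuals <- function(Y, s) {
  Y <- as.numeric(Y)
  n <- length(Y)
  s <- as.integer(s)
  if (s < 10 || s > n / 4) {
    stop("scale s must satisfy 10 <= s <= N/4 (got s = ", s, ", N = ", n, ")")
  }
  f2_windows(Y, s)
}

#' q-order fluctuation function from per-window mean-square residuals
#'
#' Generalizes the RMS fluctuation by replacing squaring/square-rooting with a
#' q-order mean: \eqn{F_q = \{ \mathrm{mean}_v (F^2_v)^{q/2} \}^{1/q}}. At
#' `q = 2` this reduces exactly to the RMS over windows.
#'
#' @param f2 Non-negative per-window mean-square residuals.
#' @param q Positive moment order.
#' @return Scalar fluctuation value (same units as the series).
#' @export
q_fluctuation <- function(f2, q) {
  if (any(f2 < 0)) stop("mean-square residuals must be non-negative")
  if (!is.finite(q) || q <= 0) stop("q must be finite and positive")
  mean(f2^(q / 2))^(1 / q)
}

#' Generalized Hurst exponent spectrum by multifractal DFA
#'
#' Runs the full multifractal detrended fluctuation analysis: integrate the
#' mean-centered series, compute linearly detrended per-window mean-square
#' residuals over a grid of window sizes (both-ends windowing), form q-order
#' fluctuation functions, and estimate each generalized Hurst exponent h(q) as
#' the OLS slope of log F_q(s) against log s. The multifractal spectrum width
#' `max(h) - min(h)` is the scalar multifractality measure: near zero for
#' monofractal signals (e.g. white noise, h ~ 0.5 at every q), large for
#' signals whose small and large fluctuations scale differently.
#'
#' @param x Numeric series or [envelope]. Must be non-constant with
#'   length >= 40.
#' @param qs Positive increasing q grid; default [default_qgrid()].
#' @param scales Integer window sizes; default [log_scales()] on `length(x)`.
#' @param n_scales Number of scales when `scales` is NULL.
#' @return An object of class `hq_spectrum`: list with `q`, `h`, `intercept`,
#'   `r2` (per-q log-log fit diagnostics), `width`, `scales`, `n`.
#' @references Kantelhardt et al. (2002) Multifractal detrended fluctuation
#'   analysis of nonstationary time series. Physica A 316, 87-114.
#' @export
#' @examples
#' set.seed(1)
#' sp <- hurst_spectrum(rnorm(2000))
#' sp$width # small: white noise is monofractal
hurst_spectrum <- function(x, qs = default_qgrid(), scales = NULL, n_scales = 19) {
  x <- as_series(x)
  n <- length(x)
  if (n < 40) stop("series too short for MFDFA: need length >= 40")
  if (any(!is.finite(x))) stop("series must be finite")
  if (stats::sd(x) == 0) stop("zero-variance series")
  check_qgrid(qs)
  if (is.null(scales)) scales <- log_scales(n, n_scales = n_scales)
  scales <- as.integer(scales)
  if (length(scales) < 4) stop("need at least 4 scales for the log-log fit")
  if (is.unsorted(scales, strictly = TRUE)) stop("scales must be strictly increasing")

  Y <- cumsum(x - mean(x))
  f2 <- lapply(scales, function(s) windowed_residuals(Y, s))

  # log F_q(s) = log( mean_v (F^2_v)^{q/2} ) / q, all q at once per scale
  logF <- t(vapply(f2, function(v) {
    log(colMeans(exp(outer(log(v), qs / 2)))) / qs
  }, numeric(length(qs))))
  if (length(qs) == 1) logF <- matrix(logF, ncol = 1)
  if (any(!is.finite(logF))) {
    stop("fluctuation function vanishes at some scale; ",
         "series has no detrendable variance there")
  }
  X <- cbind(1, log(scales))
  coef <- solve(crossprod(X), crossprod(X, logF)) # 2 x n_q
  fitted <- X %*% coef
  ss_res <- colSums((logF - fitted)^2)
  ss_tot <- colSums(sweep(logF, 2, colMeans(logF))^2)
  r2 <- 1 - ss_res / ss_tot

  h <- as.numeric(coef[2, ])
  structure(list(
    q = qs, h = h, intercept = as.numeric(coef[1, ]), r2 = as.numeric(r2),
    width = max(h) - min(h), scales = scales, n = n
  ), class = "hq_spectrum")
}

#' Multifractal spectrum width
#'
#' `max(h) - min(h)` over the q grid; zero for a perfectly monofractal h(q).
#'
#' @param hq An `hq_spectrum` (from [hurst_spectrum()]) or a numeric vector of
#'   generalized Hurst exponents with at least 2 entries.
#' @return Non-negative scalar width.
#' @export
spectrum_width <- function(hq) {
  h <- if (inherits(hq, "hq_spectrum")) hq$h else as.numeric(hq)
  if (length(h) < 2) stop("need h at >= 2 q values to measure a width")
  max(h) - min(h)
}

#' @export
print.hq_spectrum <- function(x, ...) {
  cat("Generalized Hurst spectrum (MFDFA)\n")
  cat(sprintf("  series length N = %d, %d scales in [%d, %d]\n",
              x$n, length(x$scales), min(x$scales), max(x$scales)))
  cat(sprintf("  q in [%g, %g] (%d values)\n", min(x$q), max(x$q), length(x$q)))
  cat(sprintf("  h(q_min) = %.3f, h(q_max) = %.3f\n", x$h[1], x$h[length(x$h)]))
  cat(sprintf("  spectrum width h_max - h_min = %.4f\n", x$width))
  invisible(x)
}

# Coerce an envelope or numeric vector to a plain numeric series.
as_series <- function(x) {
  if (inherits(x, "envelope")) x <- x$values
  if (!is.numeric(x)) stop("expected a numeric series or an envelope")
  as.numeric(x)
}
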