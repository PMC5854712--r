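#' IAAFT surrogate of a time series
#'
#' Generates one Iterative Amplitude Adjusted Fourier Transform surrogate:
#' starting from a random permutation of the series, iterations alternately
#' (1) impose the original amplitude spectrum on the current surrogate's
#' phases via FFT/inverse FFT and (2) replace the rank-ordered values with the
#' original's sorted values. The result shares the original's value
#' distribution exactly (rank replacement is the final step) and its amplitude
#' spectrum approximately, while nonlinear/multifractal structure is
#' destroyed — the linear null model for surrogate testing.
#'
#' Iteration stops when the relative L2 discrepancy between the surrogate's
#' and the original's amplitude spectra stops improving by more than `tol`
#' (or would increase), or after `max_iter` iterations. The per-iteration
#' discrepancy trace is attached as attribute `"trace"` and is non-increasing
#' by construction.
#'
#' @param x Finite, non-constant numeric series (or [envelope]), length >= 16.
#' @param seed Integer seed; the generator state is restored on exit.
#' @param max_iter Maximum number of IAAFT iterations.
#' @param tol Minimal relative improvement in spectral discrepancy.
#' @return Numeric surrogate series with attributes `"trace"` (spectral
#'   discrepancy per accepted iteration) and `"iterations"`.
#' @references Schreiber & Schmitz (1996) Improved surrogate data for
#'   nonlinearity tests. Phys. Rev. Lett. 77, 635.
#' @export
iaaft_surrogate <- function(x, seed = 1, max_iter = 100, tol = 1e-6) {
  x <- as_series(x)
  n <- length(x)
  if (n < 16) stop("series too short for IAAFT (need length >= 16)")
  if (any(!is.finite(x))) stop("series must be finite")
  if (stats::sd(x) == 0) stop("zero-variance series")

  r0 <- with_seed(seed, sample(x))
  res <- iaaft_core(x, r0, as.integer(max_iter), tol)
  structure(as.numeric(res$surrogate), trace = as.numeric(res$trace),
            iterations = length(res$trace))
}

#' Ensemble of IAAFT surrogates
#'
#' Derives one reproducible surrogate per member from the master `seed`
#' (member i uses seed `seed + i - 1`).
#'
#' @inheritParams iaaft_surrogate
#' @param n Ensemble size (>= 2); the study design uses 100.
#' @return Object of class `surrogate_ensemble`: list with `surrogates`
#'   (list of numeric series), `n`, `seed`, `convergence_iters`.
#' @export
surrogate_ensemble <- function(x, n = 100, seed = 1, max_iter = 100, tol = 1e-6) {
  if (n < 2) stop("ensemble needs n >= 2 surrogates")
  surr <- lapply(seq_len(n), function(i) {
    iaaft_surrogate(x, seed = seed + i - 1, max_iter = max_iter, tol = tol)
  })
  structure(list(
    surrogates = lapply(surr, as.numeric),
    n = n, seed = seed,
    convergence_iters = vapply(surr, attr, integer(1), which = "iterations")
  ), class = "surrogate_ensemble")
}

#' Surrogate significance test for multifractal spectrum width
#'
#' Computes the multifractal spectrum width of the original series and of `n`
#' IAAFT surrogates, then compares the original against the empirical
#' `[alpha/2, 1 - alpha/2]` interval of the surrogate widths. Evidence for
#' structure beyond the linear null (distribution + autocorrelation) is an
#' original width beyond the interval — the directional claim of interest is
#' width *above* the upper bound, reported separately as `significant_above`.
#' The effect size `sd_distance` is the original width's distance from the
#' ensemble mean in ensemble standard deviations.
#'
#' @param e An [envelope] or numeric series satisfying [hurst_spectrum()]'s
#'   preconditions.
#' @param n Number of surrogates (study design: 100).
#' @param alpha Two-sided significance level for the empirical interval.
#' @param qs,scales Passed to [hurst_spectrum()].
#' @param seed Master seed for the ensemble.
#' @param ci Interval type: empirical `"percentile"` (default) or
#'   `"gaussian"` (mean +/- z_{1-alpha/2} SD).
#' @param max_iter,tol IAAFT stopping parameters.
#' @return Object of class `surrogate_test`: `original_width`,
#'   `surrogate_widths`, `ci_low`, `ci_high`, `sd_distance`, `significant`
#'   (two-sided), `significant_above` (one-sided), plus settings.
#' @export
surrogate_test <- function(e, n = 100, alpha = 0.05, qs = default_qgrid(),
                           scales = NULL, seed = 1,
                           ci = c("percentile", "gaussian"),
                           max_iter = 100, tol = 1e-6) {
  ci <- match.arg(ci)
  x <- as_series(e)
  if (is.null(scales)) scales <- log_scales(length(x))
  w0 <- hurst_spectrum(x, qs = qs, scales = scales)$width
  ens <- surrogate_ensemble(x, n = n, seed = seed, max_iter = max_iter, tol = tol)
  ws <- vapply(ens$surrogates, function(s) {
    hurst_spectrum(s, qs = qs, scales = scales)$width
  }, numeric(1))
  sd_ws <- stats::sd(ws)
  if (sd_ws == 0) stop("degenerate ensemble")
  if (ci == "percentile") {
    bounds <- unname(stats::quantile(ws, c(alpha / 2, 1 - alpha / 2)))
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    bounds <- mean(ws) + c(-z, z) * sd_ws
  }
  structure(list(
    original_width = w0, surrogate_widths = ws,
    ci_low = bounds[1], ci_high = bounds[2],
    sd_distance = (w0 - mean(ws)) / sd_ws,
    significant = (w0 > bounds[2]) || (w0 < bounds[1]),
    significant_above = w0 > bounds[2],
    alpha = alpha, n = n, seed = seed, ci = ci
  ), class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat("IAAFT surrogate test of multifractal spectrum width\n")
  cat(sprintf("  original width  : %.4f\n", x$original_width))
  cat(sprintf("  surrogate %d%% CI: [%.4f, %.4f]  (n = %d)\n",
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$n))
  cat(sprintf("  SD-distance     : %.2f\n", x$sd_distance))
  cat(sprintf("  significant     : %s (above upper bound: %s)\n",
              x$significant, x$significant_above))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
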