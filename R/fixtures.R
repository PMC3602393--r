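# Surrogate-signal and synthetic-result generators.
#
# These produce EEG-like traces with known spectral content and sweep
# tables with known cluster structure, so the analysis layer (spectra,
# band powers, metrics, cluster detection) is testable in milliseconds
# without running the network. They never call the simulation modules.

#' Generate a surrogate EEG trace (sum of sinusoids plus white noise)
#'
#' A unit-amplitude sinusoid carries time-domain power `a^2 / 2`, so band
#' powers of the surrogate are analytically known.
#'
#' @param freqs component frequencies, Hz.
#' @param amps component amplitudes (recycled against `freqs`).
#' @param noise_sd standard deviation of added white Gaussian noise.
#' @param duration_ms trace length.
#' @param dt_ms sampling step.
#' @param seed RNG seed for the noise.
#' @param transient_ms transient metadata carried on the trace (default 0:
#'   surrogates have no startup transient).
#' @return an `hg_trace`.
#' @export
make_surrogate_eeg <- function(freqs = 40, amps = 1, noise_sd = 0,
                               duration_ms = 1000, dt_ms = 1, seed = 1L,
                               transient_ms = 0) {
  abort_if(dt_ms <= 0, "dt_ms must be positive")
  abort_if(length(freqs) > 0 &&
             duration_ms < 2 * 1000 / min(freqs),
           "duration must cover at least two periods of the lowest component")
  amps <- rep_len(amps, length(freqs))
  t <- seq(dt_ms, duration_ms, by = dt_ms)
  x <- numeric(length(t))
  for (i in seq_along(freqs)) {
    x <- x + amps[i] * sin(2 * pi * freqs[i] * t / 1000)
  }
  if (noise_sd > 0) {
    x <- x + with_seed(seed, rnorm(length(t), sd = noise_sd))
  }
  structure(list(t = t, x = x, dt = dt_ms,
                 meta = list(freqs = freqs, amps = amps,
                             noise_sd = noise_sd, seed = seed,
                             transient_ms = transient_ms)),
            class = "hg_trace")
}

#' Generate a synthetic sweep-result table with planted clusters
#'
#' Builds a score field over a grid as a sum of truncated linear bumps
#' (Chebyshev distance in level steps) plus optional noise, clipped to
#' `[0, 1]` — a drop-in fixture for [find_clusters()].
#'
#' @param grid data.frame of grid coordinates (one row per point; level
#'   indices are taken per column).
#' @param centers data.frame of bump centres (same columns as `grid`).
#' @param widths bump radii in level steps (recycled against centres).
#' @param heights peak scores (recycled).
#' @param noise_sd Gaussian noise on the scores.
#' @param seed RNG seed.
#' @return `grid` with a `score` column appended.
#' @export
make_synthetic_sweepresult <- function(grid, centers, widths = 1,
                                       heights = 1, noise_sd = 0,
                                       seed = 1L) {
  abort_if(nrow(grid) == 0, "grid is empty")
  lev <- lapply(grid, function(col) match(col, sort(unique(col))))
  lev <- do.call(cbind, lev)
  score <- numeric(nrow(grid))
  if (!is.null(centers) && nrow(centers) > 0) {
    widths <- rep_len(widths, nrow(centers))
    heights <- rep_len(heights, nrow(centers))
    for (k in seq_len(nrow(centers))) {
      cl <- vapply(seq_along(grid), function(j) {
        match(centers[k, j], sort(unique(grid[[j]])))
      }, numeric(1))
      abort_if(anyNA(cl), "cluster centre %d is not on the grid", k)
      d <- apply(abs(sweep(lev, 2, cl)), 1, max)
      score <- score + heights[k] * pmax(0, 1 - d / (widths[k] + 1))
    }
  }
  if (noise_sd > 0) {
    score <- score + with_seed(seed, rnorm(length(score), sd = noise_sd))
  }
  out <- grid
  out$score <- pmin(1, pmax(0, score))
  out
}
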