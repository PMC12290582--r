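# Canonical haemodynamic response function and convolution helpers.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with the standard parameter set
#' (response delay 6 s, undershoot delay 16 s, unit dispersions,
#' peak/undershoot ratio 6), truncated at `duration` and normalised to unit
#' peak. The peak sits near 5 s.
#'
#' @param dt Sampling interval of the kernel (s); use the repetition time
#'   for volume-resolution kernels or a fine interval (e.g. 0.1 s) for
#'   microtime convolution.
#' @param duration Kernel support (s).
#' @param peak_delay,undershoot_delay Gamma shape parameters (unit rate), s.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric kernel sampled at `0, dt, 2 dt, ...` with attribute `dt`;
#'   value 0 at t = 0.
#' @export
canonical_hrf <- function(dt = 1.9, duration = 32,
                          peak_delay = 6, undershoot_delay = 16,
                          ratio = 6) {
  stopifnot(dt > 0, duration > 0)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h <- h / max(h)
  structure(h, dt = dt)
}

# Linear convolution of a fine-resolution series with a kernel, truncated to
# the length of the input.
convolve_kernel <- function(x, kernel) {
  n <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(n)]
}

#' Build an HRF-convolved regressor from event onsets
#'
#' Events are placed as delta impulses on a fine time grid (event durations
#' are far below the repetition time), weighted by `amplitudes`, convolved
#' with the canonical HRF at the fine resolution, and sampled at volume
#' acquisition times.
#'
#' @param onsets Event onsets (s).
#' @param amplitudes Event weights (recycled).
#' @param n_vol Number of volumes.
#' @param tr Repetition time (s).
#' @param dt Microtime resolution (s).
#' @return Numeric vector of length `n_vol`.
#' @export
event_regressor <- function(onsets, amplitudes = 1, n_vol, tr, dt = 0.1) {
  amplitudes <- rep_len(amplitudes, length(onsets))
  n_fine <- ceiling(n_vol * tr / dt) + 1L
  x <- numeric(n_fine)
  idx <- pmin(floor(onsets / dt) + 1L, n_fine)
  for (k in seq_along(idx)) x[idx[k]] <- x[idx[k]] + amplitudes[k]
  conv <- convolve_kernel(x, canonical_hrf(dt = dt))
  vol_idx <- pmin(round((seq_len(n_vol) - 1) * tr / dt) + 1L, n_fine)
  conv[vol_idx]
}
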