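# FM-sweep waveform synthesis and verification of frequency trajectories.

#' Synthesize a phase-continuous FM-sweep
#'
#' The instantaneous frequency is `f_start` on the first plateau, linear in
#' time from `f_start` to `f_end` over the sweep segment, and `f_end` on the
#' final plateau. The phase is the cumulative integral of the instantaneous
#' frequency, so the plateau and sweep segments are merged in frequency
#' space with no phase discontinuity. Raised-cosine on/off ramps of
#' `ramp_duration` are applied to the amplitude envelope (overlapping the
#' plateaus), and the peak amplitude is normalised to `peak`.
#'
#' @param spec A [sweep_spec()].
#' @param rate Sampling rate (Hz); must be at least four times the highest
#'   frequency in the sweep.
#' @param peak Peak amplitude after normalisation (default 0.9, headroom for
#'   16-bit export).
#' @return A `waveform`: list with `samples` (in `[-1, 1]`), `rate` and the
#'   generating `spec`.
#' @examples
#' w <- synthesize_sweep(default_sweeps()$fast_up)
#' @export
synthesize_sweep <- function(spec, rate = 44100, peak = 0.9) {
  stopifnot(inherits(spec, "sweep_spec"), peak > 0, peak <= 1)
  f_max <- max(spec$f_start, spec$f_end)
  if (rate < 4 * f_max) {
    stop("sampling rate ", rate, " Hz is below 4 x max frequency (",
         4 * f_max, " Hz)")
  }
  n <- round(spec$total_duration / 1000 * rate)
  t_ms <- (seq_len(n) - 0.5) / rate * 1000  # sample-centre times
  sweep_start <- spec$plateau_duration
  sweep_end <- spec$plateau_duration + spec$sweep_duration
  f <- ifelse(t_ms < sweep_start, spec$f_start,
         ifelse(t_ms > sweep_end, spec$f_end,
           spec$f_start + spec$delta_f * (t_ms - sweep_start) /
             spec$sweep_duration))
  phase <- 2 * pi * cumsum(f) / rate
  env <- rep(1, n)
  n_ramp <- round(spec$ramp_duration / 1000 * rate)
  if (n_ramp > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 0.5) / n_ramp))
    env[seq_len(n_ramp)] <- ramp
    env[seq(n - n_ramp + 1, n)] <- rev(ramp)
  }
  samples <- env * sin(phase)
  samples <- samples / max(abs(samples)) * peak
  structure(list(samples = samples, rate = rate, spec = spec),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.1f ms)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate * 1000))
  invisible(x)
}

# Discrete analytic signal via the FFT Hilbert construction: suppress
# negative frequencies, double positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous-frequency trajectory of a waveform
#'
#' Estimates instantaneous frequency as the first difference of the analytic
#' phase (no unwrapping needed: the wrapped phase increment is read off
#' `Arg(z[t+1] * Conj(z[t]))`), divided by the sample interval.
#'
#' @param w A `waveform` (or numeric vector plus `rate`).
#' @param rate Sampling rate; taken from `w` when it is a `waveform`.
#' @return Data frame with `time` (ms, midpoints between samples) and
#'   `frequency` (Hz).
#' @export
instantaneous_frequency <- function(w, rate = NULL) {
  if (inherits(w, "waveform")) {
    x <- w$samples; rate <- w$rate
  } else {
    x <- as.numeric(w)
    if (is.null(rate)) stop("rate must be given for a bare sample vector")
  }
  if (length(x) < 16) stop("waveform too short for frequency analysis")
  z <- analytic_signal(x)
  dphi <- Arg(z[-1] * Conj(z[-length(z)]))
  data.frame(time = (seq_len(length(x) - 1) - 0.5) / rate * 1000,
             frequency = dphi * rate / (2 * pi))
}

#' Measured frequency span of a synthesized sweep
#'
#' Fits a straight line to the instantaneous-frequency trajectory over the
#' interior of the sweep segment (excluding `margin` ms next to the plateaus,
#' where ramps and the analytic-signal edges bias the estimate) and returns
#' the fitted trajectory value at the sweep end minus its value at the sweep
#' start.
#'
#' @param w A `waveform` produced by [synthesize_sweep()].
#' @param margin Interior margin (ms) excluded at both ends of the sweep
#'   segment before fitting.
#' @return Frequency span in Hz (signed).
#' @export
measure_sweep_span <- function(w, margin = 3) {
  stopifnot(inherits(w, "waveform"))
  spec <- w$spec
  traj <- instantaneous_frequency(w)
  t0 <- spec$plateau_duration
  t1 <- spec$plateau_duration + spec$sweep_duration
  sel <- traj$time >= t0 + margin & traj$time <= t1 - margin
  fit <- stats::lm(frequency ~ time, data = traj[sel, ])
  unname(diff(stats::predict(fit, data.frame(time = c(t0, t1)))))
}

#' Write a waveform as a 16-bit PCM RIFF/WAVE file
#'
#' @param w A `waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  pcm <- as.integer(round(pmax(pmin(w$samples, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
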