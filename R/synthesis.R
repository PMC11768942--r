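# Synthetic signal generation and the two corruption models
# (timing jitter, sample loss).

#' Generate a unit-power random-phase sinusoid on a dense lattice
#'
#' Draws a frequency uniformly from the resting heart-rate band and a phase
#' uniformly from `[0, 2*pi)`, then evaluates
#' `amplitude * sin(2*pi*f*t + phi)` on a regular lattice at `rate_hz`.
#' The default amplitude `sqrt(2)` makes the mean signal power exactly 1
#' on whole periods ("unit power").
#'
#' @param duration_s signal duration in seconds (default 30).
#' @param band_hz two-element vector `(f_lo, f_hi)` in Hz, `0 < f_lo < f_hi`
#'   (default `c(0.8, 1.8)`, the 48-108 bpm resting band).
#' @param amplitude peak amplitude (default `sqrt(2)`).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param rate_hz lattice rate in Hz (default 1000).
#' @param freq_hz,phase_rad optional fixed frequency/phase overriding the
#'   random draw (useful for bin-aligned test tones).
#' @return a [dense_signal()] with attributes `freq_hz` and `phase_rad`
#'   recording the realized draw.
#' @examples
#' s <- generate_sinusoid(duration_s = 30, seed = 1)
#' length(s$values)          # 30000
#' mean(s$values^2)          # ~1 (unit power)
#' @export
generate_sinusoid <- function(duration_s = 30, band_hz = c(0.8, 1.8),
                              amplitude = sqrt(2), seed = NULL,
                              rate_hz = 1000, freq_hz = NULL, phase_rad = NULL) {
  stop_if_not_number(duration_s, "duration_s", positive = TRUE)
  stop_if_not_number(amplitude, "amplitude", positive = TRUE)
  stop_if_not_number(rate_hz, "rate_hz", positive = TRUE)
  if (length(band_hz) != 2L || !all(is.finite(band_hz)) ||
      band_hz[1L] <= 0 || band_hz[1L] >= band_hz[2L]) {
    stop("`band_hz` must be (f_lo, f_hi) with 0 < f_lo < f_hi", call. = FALSE)
  }
  draw <- with_seed(seed, {
    f <- freq_hz %||% stats::runif(1L, band_hz[1L], band_hz[2L])
    phi <- phase_rad %||% stats::runif(1L, 0, 2 * pi)
    list(f = f, phi = phi)
  })
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  out <- dense_signal(amplitude * sin(2 * pi * draw$f * t + draw$phi),
                      rate_hz = rate_hz)
  attr(out, "freq_hz") <- draw$f
  attr(out, "phase_rad") <- draw$phi
  out
}

#' Generate an rPPG-like synthetic waveform
#'
#' A synthetic stand-in for a green-channel facial rPPG trace: a fundamental
#' at `hr_bpm / 60` Hz, a second harmonic scaled by `harmonic_ratio`, additive
#' white Gaussian noise, and a slow baseline wander below 0.2 Hz. With the
#' default settings the band-limited (0.8-1.8 Hz) spectral peak sits at the
#' fundamental, so the pulse rate is recoverable by [estimate_hr()].
#'
#' @param duration_s duration in seconds (default 30).
#' @param hr_bpm pulse rate in beats per minute (default 72).
#' @param harmonic_ratio amplitude of the second harmonic relative to the
#'   fundamental (default 0.3).
#' @param noise_sd standard deviation of the additive white noise
#'   (default 0.3, i.e. about -10 dB relative to the unit-power fundamental).
#' @param wander_amp amplitude of the baseline wander (default 0.5).
#' @param seed integer seed.
#' @param rate_hz lattice rate in Hz (default 1000).
#' @return a [dense_signal()] with attribute `hr_bpm`.
#' @export
generate_rppg_like <- function(duration_s = 30, hr_bpm = 72, harmonic_ratio = 0.3,
                               noise_sd = 0.3, wander_amp = 0.5, seed = NULL,
                               rate_hz = 1000) {
  stop_if_not_number(duration_s, "duration_s", positive = TRUE)
  stop_if_not_number(hr_bpm, "hr_bpm", positive = TRUE)
  stop_if_not_number(harmonic_ratio, "harmonic_ratio")
  stop_if_not_number(noise_sd, "noise_sd")
  stop_if_not_number(wander_amp, "wander_amp")
  if (harmonic_ratio < 0 || noise_sd < 0 || wander_amp < 0) {
    stop("`harmonic_ratio`, `noise_sd` and `wander_amp` must be non-negative",
         call. = FALSE)
  }
  f0 <- hr_bpm / 60
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  vals <- with_seed(seed, {
    phi0 <- stats::runif(1L, 0, 2 * pi)
    phi1 <- stats::runif(1L, 0, 2 * pi)
    f_w <- stats::runif(1L, 0.05, 0.2)
    phi_w <- stats::runif(1L, 0, 2 * pi)
    x <- sqrt(2) * sin(2 * pi * f0 * t + phi0) +
      sqrt(2) * harmonic_ratio * sin(2 * pi * 2 * f0 * t + phi1) +
      wander_amp * sin(2 * pi * f_w * t + phi_w)
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    x
  })
  out <- dense_signal(vals, rate_hz = rate_hz)
  attr(out, "hr_bpm") <- hr_bpm
  out
}

# Map times onto the dense lattice; error unless aligned within tol samples.
dense_index <- function(dense, times, tol = 1e-6, what = "grid") {
  idx <- (times - dense$start_s) * dense$rate_hz
  ridx <- round(idx)
  if (any(ridx < 0) || any(ridx > length(dense$values) - 1L)) {
    stop(sprintf("%s extends beyond the dense signal's time span", what), call. = FALSE)
  }
  if (max(abs(idx - ridx)) > tol) {
    stop(sprintf("%s timestamps do not align with the dense lattice", what), call. = FALSE)
  }
  as.integer(ridx) + 1L
}

#' Sample a dense signal regularly on a uniform grid
#'
#' Reads the dense lattice at the grid timestamps. The grid must lie within
#' the dense signal's span and align with its lattice (25 Hz on a 1 kHz
#' lattice reads every 40th sample).
#'
#' @param dense a [dense_signal()].
#' @param grid a [uniform_grid()].
#' @return a [sampled_series()] with `nominal_rate_hz = grid$rate_hz`.
#' @export
sample_regular <- function(dense, grid) {
  times <- grid_times(grid)
  idx <- dense_index(dense, times)
  sampled_series(times, dense$values[idx], nominal_rate_hz = grid$rate_hz)
}

#' Corrupt regular sampling with truncated-Gaussian timing jitter
#'
#' A seeded uniformly random subset of `floor(irregular_ratio * count)` grid
#' positions receives a capture-time bias `b ~ N(0, sigma_s^2)` clipped to
#' `[-max_bias_s, max_bias_s]`. The biased time is quantized to the dense
#' lattice (1 ms at 1 kHz); the sample's value is the dense value at that
#' biased time and its logged timestamp records the same biased time (capture
#' times are assumed to be logged exactly). Output is sorted by timestamp,
#' ties keeping original grid order; biased times falling before or after the
#' dense span are clamped to it.
#'
#' @param dense a [dense_signal()].
#' @param grid a [uniform_grid()] of nominal capture times.
#' @param spec a [jitter_spec()]; `sigma_s` and `max_bias_s` default to the
#'   grid period.
#' @return a [sampled_series()] of `grid$count` samples.
#' @export
apply_timing_jitter <- function(dense, grid, spec) {
  stopifnot(inherits(spec, "jitter_spec"))
  period <- 1 / grid$rate_hz
  sigma <- spec$sigma_s %||% period
  max_bias <- spec$max_bias_s %||% period
  times <- grid_times(grid)
  idx <- dense_index(dense, times) # validates span/alignment
  n <- grid$count
  m <- floor(spec$irregular_ratio * n)
  if (m > 0) {
    draw <- with_seed(spec$seed, {
      which_biased <- sample.int(n, m)
      bias <- stats::rnorm(m, 0, sigma)
      list(which = which_biased, bias = bias)
    })
    bias <- pmin(pmax(draw$bias, -max_bias), max_bias)
    t_biased <- times[draw$which] + bias
    # quantize to the dense lattice, clamped to its span
    j <- round((t_biased - dense$start_s) * dense$rate_hz)
    j <- pmin(pmax(j, 0), length(dense$values) - 1L)
    times[draw$which] <- dense$start_s + j / dense$rate_hz
    idx[draw$which] <- as.integer(j) + 1L
  }
  ord <- order(times) # stable: ties keep original grid order
  sampled_series(times[ord], dense$values[idx][ord], nominal_rate_hz = grid$rate_hz)
}

#' Corrupt a series by random sample loss
#'
#' Removes `loss_count` samples, chosen uniformly at random without
#' replacement. Surviving timestamps and values keep their original pairing
#' and order.
#'
#' @param series a [sampled_series()].
#' @param spec a [loss_spec()].
#' @return a [sampled_series()] of `length(series) - loss_count` samples.
#' @export
apply_sample_loss <- function(series, spec) {
  stopifnot(inherits(series, "sampled_series"), inherits(spec, "loss_spec"))
  n <- length(series$values)
  k <- spec$loss_count
  if (k >= n) stop("`loss_count` must be smaller than the series length", call. = FALSE)
  if (k == 0L) return(series)
  drop <- with_seed(spec$seed, sample.int(n, k))
  keep <- setdiff(seq_len(n), drop)
  sampled_series(series$timestamps[keep], series$values[keep],
                 nominal_rate_hz = series$nominal_rate_hz)
}
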