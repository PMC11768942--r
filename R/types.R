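# Domain containers: dense reference waveform, timestamped observation
# series, uniform target grid, and corruption specifications.

#' Dense reference waveform
#'
#' A high-rate (default 1 kHz) regularly sampled waveform that stands in for
#' the continuous rPPG signal during simulation. Downstream samplers read
#' values off this lattice rather than evaluating a closed form, so corruption
#' models remain waveform-agnostic.
#'
#' @param values numeric vector of amplitudes (arbitrary units), non-empty.
#' @param rate_hz sampling rate of the lattice in Hz (default 1000).
#' @param start_s time of the first sample in seconds (default 0).
#' @return an object of class `dense_signal` with fields `values`, `rate_hz`,
#'   `start_s`.
#' @seealso [generate_sinusoid()], [sample_regular()]
#' @export
dense_signal <- function(values, rate_hz = 1000, start_s = 0) {
  stop_if_not_number(rate_hz, "rate_hz", positive = TRUE)
  stop_if_not_number(start_s, "start_s")
  values <- as.double(values)
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  structure(
    list(values = values, rate_hz = rate_hz, start_s = start_s),
    class = "dense_signal"
  )
}

#' @export
print.dense_signal <- function(x, ...) {
  cat(sprintf(
    "<dense_signal> %d samples at %g Hz, t = [%g, %g] s\n",
    length(x$values), x$rate_hz, x$start_s, signal_end(x)
  ))
  invisible(x)
}

# last lattice time of a dense signal
signal_end <- function(dense) {
  dense$start_s + (length(dense$values) - 1L) / dense$rate_hz
}

#' Timestamped observation series
#'
#' The possibly irregular, possibly lossy sequence of logged capture times
#' \eqn{s_1 \le \dots \le s_n} and observed values \eqn{x(s_i)}. Duplicate
#' timestamps are permitted as a degenerate case; interpolators collapse them
#' by value averaging.
#'
#' @param timestamps numeric vector of capture times in seconds, finite,
#'   sorted non-decreasing.
#' @param values numeric vector of amplitudes, same length as `timestamps`.
#' @param nominal_rate_hz the configured (nominal) capture rate in Hz, or
#'   `NULL` when unknown.
#' @return an object of class `sampled_series`.
#' @export
sampled_series <- function(timestamps, values, nominal_rate_hz = NULL) {
  timestamps <- as.double(timestamps)
  values <- as.double(values)
  if (length(timestamps) < 1L) stop("series must contain at least one sample", call. = FALSE)
  if (length(timestamps) != length(values)) {
    stop("`timestamps` and `values` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(timestamps)) || any(!is.finite(values))) {
    stop("timestamps and values must be finite", call. = FALSE)
  }
  if (is.unsorted(timestamps)) {
    stop("`timestamps` must be sorted non-decreasing", call. = FALSE)
  }
  if (!is.null(nominal_rate_hz)) stop_if_not_number(nominal_rate_hz, "nominal_rate_hz", positive = TRUE)
  structure(
    list(timestamps = timestamps, values = values, nominal_rate_hz = nominal_rate_hz),
    class = "sampled_series"
  )
}

#' @export
print.sampled_series <- function(x, ...) {
  cat(sprintf(
    "<sampled_series> %d samples, t = [%g, %g] s%s\n",
    length(x$values), x$timestamps[1L], x$timestamps[length(x$timestamps)],
    if (is.null(x$nominal_rate_hz)) "" else sprintf(", nominal %g Hz", x$nominal_rate_hz)
  ))
  invisible(x)
}

#' @export
length.sampled_series <- function(x) length(x$values)

#' Uniform target grid
#'
#' The corrected time domain: `count` equally spaced timestamps
#' `start_s + i / rate_hz`, `i = 0, ..., count - 1`. At the nominal 25 Hz a
#' 30 s analysis window holds 750 grid points (40 ms period).
#'
#' @param start_s time of the first grid point in seconds.
#' @param rate_hz grid rate in Hz.
#' @param count number of grid points, positive integer.
#' @return an object of class `uniform_grid`.
#' @export
uniform_grid <- function(start_s = 0, rate_hz = 25, count = 750) {
  stop_if_not_number(start_s, "start_s")
  stop_if_not_number(rate_hz, "rate_hz", positive = TRUE)
  stop_if_not_number(count, "count", positive = TRUE)
  if (count != round(count)) stop("`count` must be an integer", call. = FALSE)
  structure(
    list(start_s = start_s, rate_hz = rate_hz, count = as.integer(count)),
    class = "uniform_grid"
  )
}

#' Timestamps of a uniform grid
#'
#' @param grid a [uniform_grid()].
#' @return numeric vector of `grid$count` timestamps in seconds.
#' @export
grid_times <- function(grid) {
  grid$start_s + (seq_len(grid$count) - 1L) / grid$rate_hz
}

#' @export
print.uniform_grid <- function(x, ...) {
  cat(sprintf(
    "<uniform_grid> %d points at %g Hz from t = %g s\n",
    x$count, x$rate_hz, x$start_s
  ))
  invisible(x)
}

#' Timing-jitter corruption specification
#'
#' A fraction `irregular_ratio` of samples receives a capture-time bias drawn
#' from a zero-mean Gaussian with standard deviation `sigma_s`, clipped to
#' `[-max_bias_s, max_bias_s]`. The defaults (both equal to the nominal
#' sampling period, filled in by [apply_timing_jitter()]) model a camera whose
#' frame intervals wander by up to one full frame period.
#'
#' @param irregular_ratio fraction of samples biased, in `[0, 1]`.
#' @param sigma_s bias standard deviation in seconds, or `NULL` for the
#'   nominal sampling period.
#' @param max_bias_s clipping bound in seconds, or `NULL` for the nominal
#'   sampling period.
#' @param seed integer seed controlling which samples are biased and by how
#'   much, or `NULL` to use the current RNG stream.
#' @return an object of class `jitter_spec`.
#' @export
jitter_spec <- function(irregular_ratio, sigma_s = NULL, max_bias_s = NULL, seed = NULL) {
  stop_if_not_number(irregular_ratio, "irregular_ratio")
  if (irregular_ratio < 0 || irregular_ratio > 1) {
    stop("`irregular_ratio` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(sigma_s)) stop_if_not_number(sigma_s, "sigma_s", positive = TRUE)
  if (!is.null(max_bias_s)) stop_if_not_number(max_bias_s, "max_bias_s", positive = TRUE)
  structure(
    list(irregular_ratio = irregular_ratio, sigma_s = sigma_s,
         max_bias_s = max_bias_s, seed = seed),
    class = "jitter_spec"
  )
}

#' Sample-loss corruption specification
#'
#' `loss_count` samples are removed uniformly at random, without replacement,
#' from anywhere in the series (endpoints included). Surviving samples keep
#' their original timestamps and values.
#'
#' @param loss_count non-negative integer number of samples to drop.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return an object of class `loss_spec`.
#' @export
loss_spec <- function(loss_count, seed = NULL) {
  stop_if_not_number(loss_count, "loss_count")
  if (loss_count < 0 || loss_count != round(loss_count)) {
    stop("`loss_count` must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(loss_count = as.integer(loss_count), seed = seed),
    class = "loss_spec"
  )
}
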