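# Heart-rate estimation chain: ROI green-channel averaging, FFT magnitude
# spectrum, and dominant-frequency read-out in the resting band.

#' Resting heart-rate frequency band
#'
#' The spectral search window for the dominant pulse frequency. The default
#' 0.8-1.8 Hz targets resting adult heart rates (48-108 bpm).
#'
#' @param f_lo_hz lower edge in Hz (default 0.8).
#' @param f_hi_hz upper edge in Hz (default 1.8).
#' @return an object of class `spectrum_band`.
#' @export
spectrum_band <- function(f_lo_hz = 0.8, f_hi_hz = 1.8) {
  stop_if_not_number(f_lo_hz, "f_lo_hz", positive = TRUE)
  stop_if_not_number(f_hi_hz, "f_hi_hz", positive = TRUE)
  if (f_lo_hz >= f_hi_hz) stop("`f_lo_hz` must be below `f_hi_hz`", call. = FALSE)
  structure(list(f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz), class = "spectrum_band")
}

#' Fractional region of interest within a video frame
#'
#' Rectangle in fractional frame coordinates (0 = top/left edge,
#' 1 = bottom/right edge). Face detection is out of scope: callers supply the
#' facial ROI (typically the region between eyes and mouth).
#'
#' @param top,bottom fractional row bounds, `0 <= top < bottom <= 1`.
#' @param left,right fractional column bounds, `0 <= left < right <= 1`.
#' @return an object of class `roi_box`.
#' @export
roi_box <- function(top = 0, bottom = 1, left = 0, right = 1) {
  for (nm in c("top", "bottom", "left", "right")) stop_if_not_number(get(nm), nm)
  if (top >= bottom || left >= right) {
    stop("ROI must satisfy top < bottom and left < right", call. = FALSE)
  }
  if (top < 0 || bottom > 1 || left < 0 || right > 1) {
    stop("ROI bounds must lie in [0, 1]", call. = FALSE)
  }
  structure(list(top = top, bottom = bottom, left = left, right = right),
            class = "roi_box")
}

#' Mean green-channel intensity over a region of interest
#'
#' Averages the green channel of one video frame over the pixels covered by
#' the fractional ROI. The green channel carries the strongest blood-volume
#' signal, so this scalar per frame is the raw rPPG sample.
#'
#' @param frame an `H x W x 3` numeric array.
#' @param roi an [roi_box()].
#' @param channel_order `"rgb"` or `"bgr"`: the frame's channel convention
#'   (the green channel is the second plane in both, but the flag documents
#'   the caller's convention and guards future orderings).
#' @return the scalar mean green value over the ROI.
#' @export
green_channel_mean <- function(frame, roi = roi_box(),
                               channel_order = c("rgb", "bgr")) {
  channel_order <- match.arg(channel_order)
  stopifnot(inherits(roi, "roi_box"))
  dm <- dim(frame)
  if (length(dm) != 3L || dm[3L] != 3L) {
    stop("`frame` must be an H x W x 3 array", call. = FALSE)
  }
  h <- dm[1L]; w <- dm[2L]
  rows <- (floor(roi$top * h) + 1L):ceiling(roi$bottom * h)
  cols <- (floor(roi$left * w) + 1L):ceiling(roi$right * w)
  if (length(rows) < 1L || length(cols) < 1L ||
      rows[1L] > h || cols[1L] > w) {
    stop("ROI rounds to zero pixels for this frame size", call. = FALSE)
  }
  green <- 2L # second plane in both RGB and BGR order
  mean(frame[rows, cols, green])
}

#' One-sided FFT magnitude spectrum
#'
#' Removes the mean, applies no taper window and no zero padding, and returns
#' the one-sided magnitude spectrum at bins `k * rate_hz / n`,
#' `k = 0, ..., floor(n/2)`. With 750 samples at 25 Hz the bin width is
#' 1/30 Hz, i.e. 2 bpm.
#'
#' @param values numeric vector, length at least 2, assumed uniformly sampled.
#' @param rate_hz sampling rate in Hz.
#' @return a list with `freqs_hz` and `magnitudes` (raw FFT magnitudes).
#' @export
power_spectrum <- function(values, rate_hz) {
  values <- as.double(values)
  stop_if_not_number(rate_hz, "rate_hz", positive = TRUE)
  if (length(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  n <- length(values)
  x <- values - mean(values)
  mags <- Mod(stats::fft(x))
  half <- floor(n / 2)
  k <- 0:half
  list(freqs_hz = k * rate_hz / n, magnitudes = mags[k + 1L])
}

#' Dominant-frequency heart-rate estimate
#'
#' Restricts the one-sided spectrum to the resting band and reads the
#' frequency of maximum magnitude; ties are broken toward the lowest
#' frequency. Heart rate is `60 * f_peak` bpm.
#'
#' @param values numeric vector of uniformly sampled signal values.
#' @param rate_hz sampling rate in Hz.
#' @param band a [spectrum_band()].
#' @return an object of class `hr_result` with fields `hr_bpm`, `f_peak_hz`,
#'   `freqs_hz` and `magnitudes` (the band-restricted spectrum).
#' @examples
#' t <- (0:749) / 25
#' r <- estimate_hr(sin(2 * pi * 1.2 * t), 25)
#' r$hr_bpm # 72
#' @export
estimate_hr <- function(values, rate_hz, band = spectrum_band()) {
  stopifnot(inherits(band, "spectrum_band"))
  if (band$f_hi_hz >= rate_hz / 2) {
    stop("band must lie below the Nyquist frequency", call. = FALSE)
  }
  spec <- power_spectrum(values, rate_hz)
  sel <- spec$freqs_hz >= band$f_lo_hz & spec$freqs_hz <= band$f_hi_hz
  if (!any(sel)) stop("no FFT bin falls inside the requested band", call. = FALSE)
  freqs <- spec$freqs_hz[sel]
  mags <- spec$magnitudes[sel]
  peak <- which.max(mags) # first maximum = lowest frequency on ties
  structure(
    list(hr_bpm = 60 * freqs[peak], f_peak_hz = freqs[peak],
         freqs_hz = freqs, magnitudes = mags),
    class = "hr_result"
  )
}

#' @export
print.hr_result <- function(x, ...) {
  cat(sprintf("<hr_result> %.2f bpm (peak %.4f Hz, %d band bins)\n",
              x$hr_bpm, x$f_peak_hz, length(x$freqs_hz)))
  invisible(x)
}

#' Heart rate from a timestamped series, with optional timing correction
#'
#' `method = "none"` is the uncorrected baseline: the values are treated as
#' if uniformly sampled at the grid's nominal rate, timestamps ignored. This
#' is what makes uncorrected sample loss compress the time axis and shift the
#' dominant frequency. Any other method first reconstructs the series onto
#' the uniform grid via [reconstruct()].
#'
#' @param series a [sampled_series()].
#' @param method one of `"none"`, `"linear"`, `"cubic"`, `"cic"`.
#' @param grid a [uniform_grid()]; its rate is the nominal analysis rate and
#'   its count the FFT length for the corrected methods.
#' @param band a [spectrum_band()].
#' @param cfg a [cic_config()] for `method = "cic"`.
#' @return an `hr_result`.
#' @export
estimate_hr_from_series <- function(series,
                                    method = c("none", "linear", "cubic", "cic"),
                                    grid = uniform_grid(), band = spectrum_band(),
                                    cfg = cic_config()) {
  method <- match.arg(method)
  if (method == "none") {
    return(estimate_hr(series$values, grid$rate_hz, band))
  }
  vals <- reconstruct(series, grid, method, cfg)
  estimate_hr(vals, grid$rate_hz, band)
}
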