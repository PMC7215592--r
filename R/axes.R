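#' Frequency axis in wavenumbers
#'
#' A validated, strictly increasing, uniformly spaced grid of wavenumbers
#' (cm^-1). Both the excitation and the emission axis of a 2D map are
#' `frequency_axis` objects, as is the beat-frequency axis of a Fourier
#' spectrum of coherences.
#'
#' @param values Numeric vector of wavenumbers, cm^-1. Must be strictly
#'   increasing with uniform spacing (relative spacing deviation below 1e-6)
#'   and have at least 8 points.
#' @return A numeric vector of class `"frequency_axis"`.
#' @examples
#' ax <- frequency_axis(seq(13800, 17600, length.out = 96))
#' axis_step(ax)
#' @export
frequency_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 8L) {
    stop("frequency_axis needs at least 8 points, got ", length(values))
  }
  .check_uniform_increasing(values, "frequency_axis")
  structure(values, class = "frequency_axis")
}

#' Population-time axis
#'
#' A validated, strictly increasing, uniformly spaced grid of population
#' times t2 (fs). A full scan starts at 0; an axis truncated by a fit window
#' (e.g. after discarding the pulse-overlap region) may start later.
#'
#' @param values Numeric vector of times, fs; strictly increasing, uniform
#'   spacing, at least 2 points.
#' @return A numeric vector of class `"time_axis"`.
#' @examples
#' t2 <- time_axis(seq(0, 997.5, by = 7.5))
#' @export
time_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("time_axis needs at least 2 points, got ", length(values))
  }
  .check_uniform_increasing(values, "time_axis")
  structure(values, class = "time_axis")
}

.check_uniform_increasing <- function(values, what) {
  if (any(!is.finite(values))) stop(what, ": all values must be finite")
  d <- diff(values)
  if (any(d <= 0)) stop(what, ": values must be strictly increasing")
  step <- mean(d)
  if (max(abs(d - step)) > 1e-6 * step) {
    stop(what, ": spacing must be uniform (max deviation ",
         format(max(abs(d - step))), " exceeds 1e-6 of step ",
         format(step), ")")
  }
  invisible(values)
}

#' Grid step of a uniform axis
#'
#' @param axis A `frequency_axis` or `time_axis` (or any uniform numeric grid).
#' @return The (mean) spacing between consecutive points.
#' @export
axis_step <- function(axis) mean(diff(as.numeric(axis)))

#' Convert a wavelength in nm to a wavenumber in cm^-1
#'
#' @param lambda_nm Wavelength in nanometers, > 0.
#' @return Wavenumber 1e7 / lambda_nm, cm^-1.
#' @examples
#' wavelength_nm_to_wavenumber(650) # Qy(0,0) band of chlorophyll b
#' @export
wavelength_nm_to_wavenumber <- function(lambda_nm) {
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0)) {
    stop("wavelength must be positive and finite")
  }
  1e7 / lambda_nm
}

#' Convert a wavenumber in cm^-1 to a wavelength in nm
#'
#' Inverse of [wavelength_nm_to_wavenumber()].
#'
#' @param nu_cm1 Wavenumber in cm^-1, > 0.
#' @return Wavelength in nm.
#' @export
wavenumber_to_wavelength_nm <- function(nu_cm1) {
  if (any(!is.finite(nu_cm1)) || any(nu_cm1 <= 0)) {
    stop("wavenumber must be positive and finite")
  }
  1e7 / nu_cm1
}

#' Transform-limited spectral bandwidth of a Gaussian pulse
#'
#' For a Gaussian pulse the product of intensity-FWHM duration and
#' intensity-FWHM spectral width is 2*ln(2)/pi (~0.4413). Given the duration
#' this returns the transform-limited bandwidth in wavenumbers; a 10 fs pulse
#' corresponds to about 1471 cm^-1.
#'
#' @param dt_fs Intensity FWHM pulse duration, fs, > 0.
#' @return Spectral FWHM in cm^-1, monotonically decreasing in `dt_fs`.
#' @examples
#' transform_limited_gaussian_bandwidth(10)
#' @export
transform_limited_gaussian_bandwidth <- function(dt_fs) {
  if (any(!is.finite(dt_fs)) || any(dt_fs <= 0)) {
    stop("pulse duration must be positive and finite")
  }
  GAUSSIAN_TBP / (dt_fs * C_CM_PER_FS)
}

#' Non-negative DFT frequency axis in wavenumbers
#'
#' Builds the non-negative discrete-Fourier frequency grid for a real signal
#' of `n` samples at step `dt` fs, optionally zero-padded by an integer
#' factor, converted from fs^-1 to cm^-1 through the speed of light. The last
#' point is the Nyquist frequency 1/(2*dt*c).
#'
#' @param dt Sampling step along t2, fs, > 0.
#' @param n Number of samples before padding, >= 2.
#' @param pad_factor Integer zero-padding factor, >= 1 (default 1).
#' @return A `frequency_axis` of beat wavenumbers from 0 to Nyquist,
#'   spacing 1/(n*pad_factor*dt*c) cm^-1.
#' @examples
#' fft_wavenumber_axis(7.5, 134, pad_factor = 4)[1:5]
#' @export
fft_wavenumber_axis <- function(dt, n, pad_factor = 1L) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  n <- as.integer(n)
  pad_factor <- as.integer(pad_factor)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
  if (is.na(pad_factor) || pad_factor < 1L) stop("pad_factor must be an integer >= 1")
  n_fft <- n * pad_factor
  k <- 0:(n_fft %/% 2L)
  values <- k / (n_fft * dt * C_CM_PER_FS)
  structure(as.numeric(values), class = "frequency_axis")
}
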