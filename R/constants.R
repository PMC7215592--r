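#' Physical constants used throughout the package
#'
#' `C_CM_PER_FS` is the speed of light in cm/fs, the single conversion factor
#' between wavenumbers (cm^-1) and femtosecond time scales used by every
#' module. `GAUSSIAN_TBP` is the Gaussian intensity-FWHM time-bandwidth
#' product, 2*ln(2)/pi.
#'
#' @name constants
#' @keywords internal
NULL

#' @rdname constants
#' @export
C_CM_PER_FS <- 2.99792458e-5

#' @rdname constants
#' @export
GAUSSIAN_TBP <- 2 * log(2) / pi
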