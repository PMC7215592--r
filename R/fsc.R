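#' Configuration of the Fourier-spectrum-of-coherences analysis
#'
#' @param window_function Apodization applied along t2 before the transform:
#'   `"hann"` (default, suppresses truncation leakage of the ~1 ps window)
#'   or `"none"`.
#' @param pad_factor Integer zero-padding factor, >= 1 (default 4, giving a
#'   ~8.3 cm^-1 bin for the default 7.5 fs / 134-point scan).
#' @param normalize_input Divide the dataset by its global maximum before
#'   fitting/residues (default TRUE), so beat amplitudes from different
#'   measurements are comparable. Applied by [fsc_pipeline()].
#' @param aggregate Combine per-pixel amplitude spectra by their `"mean"`
#'   (default) or `"sum"`. The mean of magnitudes (not the magnitude of the
#'   mean) is used so spatially anti-phased beats do not cancel.
#' @return A list of class `"fsc_config"`.
#' @export
fsc_config <- function(window_function = c("hann", "none"), pad_factor = 4L,
                       normalize_input = TRUE, aggregate = c("mean", "sum")) {
  window_function <- match.arg(window_function)
  aggregate <- match.arg(aggregate)
  pad_factor <- as.integer(pad_factor)
  if (is.na(pad_factor) || pad_factor < 1L) stop("pad_factor must be >= 1")
  structure(list(window_function = window_function, pad_factor = pad_factor,
                 normalize_input = isTRUE(normalize_input),
                 aggregate = aggregate),
            class = "fsc_config")
}

.apodization <- function(kind, n) {
  switch(kind,
         hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))),
         none = rep(1, n))
}

# per-pixel one-sided magnitude spectra of the residues:
# list(frequency, amp = (n_bins x n_pixels) matrix)
.fsc_matrix <- function(res, config) {
  stopifnot(inherits(res, "dataset_2des"))
  t2 <- as.numeric(res$time)
  nt <- length(t2)
  if (nt < 16L) stop("need at least 16 time points for the FSC, got ", nt)
  dt <- axis_step(res$time)
  d <- dim(res$cube)
  M <- matrix(res$cube, d[1] * d[2], d[3])          # pixels x time
  w <- .apodization(config$window_function, nt)
  Mw <- sweep(M, 2L, w, `*`)
  n_fft <- nt * config$pad_factor
  G <- matrix(0, n_fft, nrow(Mw))
  G[1:nt, ] <- t(Mw)
  spec <- Mod(stats::mvfft(G))[1:(n_fft %/% 2L + 1L), , drop = FALSE]
  list(frequency = fft_wavenumber_axis(dt, nt, config$pad_factor),
       amp = spec, n1 = d[1], n3 = d[2])
}

#' Fourier spectrum of coherences
#'
#' Transforms the oscillating residues along t2 into an aggregated
#' beat-amplitude spectrum: per pixel, the residues are apodized,
#' zero-padded, discrete-Fourier transformed and their magnitudes taken;
#' the per-pixel magnitude spectra are then averaged (or summed) over all
#' pixels. Peaks mark vibrational coherence frequencies.
#'
#' @param res A `dataset_2des` of residues (uniform time axis, >= 16
#'   points), as returned by [residues()].
#' @param config An `fsc_config`.
#' @return A list of class `"coherence_spectrum"`: `frequency`
#'   (`frequency_axis`, 0 to Nyquist, cm^-1) and `amplitude` (>= 0).
#' @export
compute_fsc <- function(res, config = fsc_config()) {
  px <- .fsc_matrix(res, config)
  amp <- switch(config$aggregate,
                mean = rowMeans(px$amp),
                sum = rowSums(px$amp))
  structure(list(frequency = px$frequency, amplitude = amp),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %d bins, 0-%.0f cm^-1, max amplitude %.4g\n",
              length(x$frequency), max(x$frequency), max(x$amplitude)))
  invisible(x)
}

#' Beat map at one frequency
#'
#' Per-pixel beat amplitude at the padded-FFT bin nearest `nu`: the spatial
#' distribution over (omega1, omega3) of the oscillation at one vibrational
#' frequency.
#'
#' @param res A `dataset_2des` of residues.
#' @param nu Beat wavenumber, cm^-1, between 0 and the t2 Nyquist frequency.
#' @param config An `fsc_config`.
#' @return A list of class `"beat_map"`: `nu` (the bin center actually used,
#'   cm^-1) and `map` (a `map2d` of beat amplitude).
#' @export
beat_map <- function(res, nu, config = fsc_config()) {
  px <- .fsc_matrix(res, config)
  nyquist <- max(px$frequency)
  if (nu < 0 || nu > nyquist) {
    stop("nu must lie in [0, ", format(nyquist, digits = 6), "] cm^-1")
  }
  k <- .nearest_index(as.numeric(px$frequency), nu)
  m <- map2d(res$excitation, res$emission, matrix(px$amp[k, ], px$n1, px$n3))
  structure(list(nu = as.numeric(px$frequency)[k], map = m), class = "beat_map")
}

#' Pick peaks of a coherence spectrum
#'
#' Finds local maxima above `min_frequency` and scores each by its
#' prominence above the spectrum's incoherent noise floor. Averaging
#' per-pixel magnitude spectra leaves an additive, nearly flat floor (the
#' expected magnitude of the noise), so the floor is estimated as the median
#' amplitude above `min_frequency` and subtracted before thresholding:
#' peaks are kept when `amplitude - floor >= min_prominence_rel *
#' (max - floor)`. This makes detection independent of the floor height,
#' which carries no beat information. In addition, peaks must rise at least
#' 5 robust standard deviations (1.4826 x MAD) above the floor, the
#' conventional gate against ripples of the noise floor itself. Peak
#' frequencies are refined by 3-point parabolic interpolation.
#'
#' @param spec A `coherence_spectrum`.
#' @param min_prominence_rel Threshold as a fraction of the floor-corrected
#'   spectrum maximum (default 0.1).
#' @param min_frequency Ignore structure below this wavenumber, cm^-1
#'   (default 100): the slowly varying kinetic residual concentrates there.
#' @return A data.frame of class `"peak_list"` with columns `nu_cm1`,
#'   `amplitude` (raw interpolated amplitude) and `prominence` (height above
#'   the noise floor), sorted by `nu_cm1`. May be empty.
#' @export
pick_peaks <- function(spec, min_prominence_rel = 0.1, min_frequency = 100) {
  stopifnot(inherits(spec, "coherence_spectrum"))
  f <- as.numeric(spec$frequency); a <- spec$amplitude
  n <- length(a)
  cand <- which(a[-c(1L, n)] > a[-c(n - 1L, n)] &
                a[-c(1L, n)] >= a[-c(1L, 2L)]) + 1L
  cand <- cand[f[cand] >= min_frequency]
  sel <- if (any(f >= min_frequency)) a[f >= min_frequency] else a
  floor_level <- stats::median(sel)
  thresh <- max(min_prominence_rel * (max(sel) - floor_level),
                5 * stats::mad(sel))

  rows <- list()
  for (i in cand) {
    prom <- a[i] - floor_level
    if (prom < thresh || prom <= 0) next
    ref <- .parabolic_refine(f, a, i)
    rows[[length(rows) + 1L]] <- c(ref$x, ref$value, prom)
  }
  df <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else {
    data.frame(V1 = numeric(0), V2 = numeric(0), V3 = numeric(0))
  }
  names(df) <- c("nu_cm1", "amplitude", "prominence")
  df <- df[order(df$nu_cm1), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Full coherence pipeline: fit, residues, FSC
#'
#' Convenience wrapper chaining the stages of the coherence analysis:
#' optional normalization of the dataset by its global maximum (so beat
#' amplitudes are comparable across measurements), multi-exponential global
#' fit, residue extraction, and the Fourier spectrum of coherences.
#'
#' @param ds A `dataset_2des`.
#' @param fit_config A `global_fit_config`.
#' @param config An `fsc_config`.
#' @param fit Optionally a precomputed `global_fit_result` for `ds` (the
#'   normalization is then assumed to match `config$normalize_input`).
#' @return A list with `spectrum` (`coherence_spectrum`), `fit`
#'   (`global_fit_result`) and `residues` (`dataset_2des`).
#' @export
fsc_pipeline <- function(ds, fit_config = global_fit_config(),
                         config = fsc_config(), fit = NULL) {
  stopifnot(inherits(ds, "dataset_2des"))
  if (config$normalize_input && is.null(fit)) {
    ds <- dataset_2des(ds$excitation, ds$emission, ds$time,
                       ds$cube / max(abs(ds$cube)), ds$meta)
  }
  if (is.null(fit)) fit <- fit_global(ds, fit_config)
  res <- residues(ds, fit)
  list(spectrum = compute_fsc(res, config), fit = fit, residues = res)
}
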