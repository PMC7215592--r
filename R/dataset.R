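#' 2D frequency-frequency map
#'
#' A single absorptive 2D spectrum: a real amplitude matrix over
#' (excitation, emission) wavenumber axes. Rows index the excitation axis,
#' columns the emission axis.
#'
#' @param excitation,emission `frequency_axis` objects (or numeric vectors
#'   coerced to them), cm^-1.
#' @param amplitude Real matrix, `length(excitation)` x `length(emission)`,
#'   all finite. Arbitrary signal units.
#' @return A list of class `"map2d"` with elements `excitation`, `emission`,
#'   `amplitude`.
#' @export
map2d <- function(excitation, emission, amplitude) {
  if (!inherits(excitation, "frequency_axis")) excitation <- frequency_axis(excitation)
  if (!inherits(emission, "frequency_axis")) emission <- frequency_axis(emission)
  amplitude <- as.matrix(amplitude)
  if (!all(dim(amplitude) == c(length(excitation), length(emission)))) {
    stop("amplitude must be ", length(excitation), " x ", length(emission),
         ", got ", paste(dim(amplitude), collapse = " x "))
  }
  if (any(!is.finite(amplitude))) stop("map2d amplitude must be finite everywhere")
  structure(list(excitation = excitation, emission = emission,
                 amplitude = amplitude),
            class = "map2d")
}

#' @export
print.map2d <- function(x, ...) {
  cat(sprintf("<map2d> %d x %d pixels, excitation %.0f-%.0f cm^-1, emission %.0f-%.0f cm^-1\n",
              length(x$excitation), length(x$emission),
              min(x$excitation), max(x$excitation),
              min(x$emission), max(x$emission)))
  cat(sprintf("  amplitude range [%.4g, %.4g]\n",
              min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

#' 2DES dataset: a stack of 2D maps versus population time
#'
#' The central container of the package: a real 3D array over
#' (excitation, emission, population time). Axis order is fixed as
#' (excitation, emission, time) everywhere, including the file format.
#'
#' @param excitation,emission `frequency_axis` objects, cm^-1.
#' @param time `time_axis` of population times t2, fs.
#' @param cube Real 3D array, dimensions
#'   `length(excitation) x length(emission) x length(time)`, all finite.
#' @param meta Named list of free-form metadata (preset name, temperature
#'   label, seed, ...).
#' @return A list of class `"dataset_2des"`.
#' @export
dataset_2des <- function(excitation, emission, time, cube, meta = list()) {
  if (!inherits(excitation, "frequency_axis")) excitation <- frequency_axis(excitation)
  if (!inherits(emission, "frequency_axis")) emission <- frequency_axis(emission)
  if (!inherits(time, "time_axis")) time <- time_axis(time)
  if (!is.array(cube) || length(dim(cube)) != 3L) {
    stop("cube must be a 3D array (excitation x emission x time)")
  }
  expected <- c(length(excitation), length(emission), length(time))
  if (!all(dim(cube) == expected)) {
    stop("cube dimensions ", paste(dim(cube), collapse = " x "),
         " do not match axes ", paste(expected, collapse = " x "))
  }
  if (any(!is.finite(cube))) stop("cube must be finite everywhere")
  structure(list(excitation = excitation, emission = emission, time = time,
                 cube = cube, meta = meta),
            class = "dataset_2des")
}

#' @export
print.dataset_2des <- function(x, ...) {
  cat(sprintf("<dataset_2des> %d x %d pixels, %d population times (%.1f-%.1f fs)\n",
              length(x$excitation), length(x$emission), length(x$time),
              min(x$time), max(x$time)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract one population-time slice as a map2d
#'
#' @param ds A `dataset_2des`.
#' @param t2 Population time, fs; the nearest sampled t2 is used (ties toward
#'   the earlier time).
#' @return A `map2d`.
#' @export
slice_map <- function(ds, t2) {
  stopifnot(inherits(ds, "dataset_2des"))
  k <- which.min(abs(as.numeric(ds$time) - t2))
  map2d(ds$excitation, ds$emission, ds$cube[, , k])
}

#' Extract the time trace at one (excitation, emission) coordinate
#'
#' Returns the trace of the pixel nearest to the requested coordinates
#' (nearest-pixel, no interpolation; ties broken toward the lower index).
#'
#' @param ds A `dataset_2des`.
#' @param omega1 Excitation wavenumber, cm^-1; must lie within the axis range.
#' @param omega3 Emission wavenumber, cm^-1; must lie within the axis range.
#' @return A data.frame with columns `t2_fs` and `signal`, with attributes
#'   `omega1` and `omega3` giving the actual pixel coordinates used.
#' @export
slice_trace <- function(ds, omega1, omega3) {
  stopifnot(inherits(ds, "dataset_2des"))
  ex <- as.numeric(ds$excitation); em <- as.numeric(ds$emission)
  if (omega1 < min(ex) || omega1 > max(ex)) {
    stop("excitation coordinate ", omega1, " outside axis range [",
         min(ex), ", ", max(ex), "]")
  }
  if (omega3 < min(em) || omega3 > max(em)) {
    stop("emission coordinate ", omega3, " outside axis range [",
         min(em), ", ", max(em), "]")
  }
  i <- .nearest_index(ex, omega1)
  j <- .nearest_index(em, omega3)
  out <- data.frame(t2_fs = as.numeric(ds$time), signal = ds$cube[i, j, ])
  attr(out, "omega1") <- ex[i]
  attr(out, "omega3") <- em[j]
  out
}

# nearest grid index with ties broken toward the lower index
.nearest_index <- function(axis, value) {
  d <- abs(axis - value)
  which(d <= min(d) + 1e-9 * max(1, abs(value)))[1L]
}

#' Locate an extremum of a 2D map with sub-pixel refinement
#'
#' Finds the maximal (or minimal) pixel, optionally within an axis-aligned
#' rectangular window, then refines each coordinate independently by a
#' 3-point parabolic interpolation through the extremal pixel and its two
#' neighbours along that axis (refinement is skipped at grid edges).
#'
#' @param map A `map2d`.
#' @param mode `"max"` or `"min"`.
#' @param window Optional window `list(excitation = c(lo, hi),
#'   emission = c(lo, hi))` in cm^-1; either element may be omitted. The
#'   window must overlap the grid by at least 3 x 3 pixels.
#' @return A list with `omega1`, `omega3` (refined coordinates, cm^-1) and
#'   `value` (parabolically interpolated amplitude).
#' @examples
#' ax <- seq(14000, 17000, length.out = 64)
#' m <- render_feature(gaussian2d_feature(c(15400, 15200), 260, 260, 0, 1),
#'                     ax, ax)
#' locate_extremum(m, "max")
#' @export
locate_extremum <- function(map, mode = c("max", "min"), window = NULL) {
  stopifnot(inherits(map, "map2d"))
  mode <- match.arg(mode)
  ex <- as.numeric(map$excitation); em <- as.numeric(map$emission)
  ii <- seq_along(ex); jj <- seq_along(em)
  if (!is.null(window)) {
    if (!is.null(window$excitation)) {
      ii <- which(ex >= window$excitation[1] & ex <= window$excitation[2])
    }
    if (!is.null(window$emission)) {
      jj <- which(em >= window$emission[1] & em <= window$emission[2])
    }
    if (length(ii) < 3L || length(jj) < 3L) {
      stop("window must overlap the grid by at least 3 x 3 pixels (got ",
           length(ii), " x ", length(jj), ")")
    }
  }
  a <- map$amplitude[ii, jj, drop = FALSE]
  if (mode == "min") a <- -a
  k <- arrayInd(which.max(a), dim(a))
  i0 <- ii[k[1]]; j0 <- jj[k[2]]

  ref1 <- .parabolic_refine(ex, map$amplitude[, j0] * (if (mode == "min") -1 else 1), i0)
  ref3 <- .parabolic_refine(em, map$amplitude[i0, ] * (if (mode == "min") -1 else 1), j0)
  value <- max(ref1$value, ref3$value)
  if (mode == "min") value <- -value
  list(omega1 = ref1$x, omega3 = ref3$x, value = value)
}

# 3-point parabolic sub-grid refinement of a local maximum at index i0;
# returns the grid point unchanged at edges or for degenerate curvature.
.parabolic_refine <- function(x, y, i0) {
  n <- length(x)
  if (i0 <= 1L || i0 >= n) return(list(x = x[i0], value = y[i0]))
  ym <- y[i0 - 1L]; y0 <- y[i0]; yp <- y[i0 + 1L]
  denom <- ym - 2 * y0 + yp
  if (denom >= 0 || abs(denom) < .Machine$double.eps * max(abs(c(ym, y0, yp)), 1)) {
    return(list(x = x[i0], value = y0))
  }
  delta <- 0.5 * (ym - yp) / denom
  delta <- max(-0.5, min(0.5, delta))
  step <- x[i0 + 1L] - x[i0]
  list(x = x[i0] + delta * step, value = y0 - 0.25 * (ym - yp) * delta)
}
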