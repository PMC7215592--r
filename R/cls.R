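#' Configuration of the center-line-slope analysis
#'
#' @param window Optional window `list(excitation = c(lo, hi),
#'   emission = c(lo, hi))`, cm^-1, around the diagonal peak. When NULL the
#'   window is derived from the first (t2 = 0) slice: peak center +/- 1.2 x
#'   FWHM on both axes.
#' @param column_method `"parabolic"` (3-point parabolic refinement of each
#'   column maximum, the default) or `"centroid"` (intensity centroid of the
#'   column, more robust for flat-topped peaks).
#' @param min_rel_intensity Columns whose maximum falls below this fraction
#'   of the slice maximum inside the window are excluded (default 0.2).
#' @param weighted Weight columns by their maximum in the line fit (default
#'   TRUE); unweighted least squares when FALSE.
#' @return A list of class `"cls_config"`.
#' @export
cls_config <- function(window = NULL,
                       column_method = c("parabolic", "centroid"),
                       min_rel_intensity = 0.2, weighted = TRUE) {
  column_method <- match.arg(column_method)
  if (!(min_rel_intensity > 0 && min_rel_intensity < 1)) {
    stop("min_rel_intensity must be in (0, 1)")
  }
  structure(list(window = window, column_method = column_method,
                 min_rel_intensity = min_rel_intensity,
                 weighted = isTRUE(weighted)),
            class = "cls_config")
}

# FWHM of a 1D profile around its maximum, by linear interpolation of the
# half-maximum crossings; falls back to the distance to the window edge.
.profile_fwhm <- function(x, y) {
  i0 <- which.max(y)
  half <- y[i0] / 2
  left <- x[1]; right <- x[length(x)]
  if (i0 > 1L) {
    below <- which(y[1:(i0 - 1L)] < half)
    if (length(below)) {
      i <- max(below)
      left <- x[i] + (x[i + 1L] - x[i]) * (half - y[i]) / (y[i + 1L] - y[i])
    }
  }
  if (i0 < length(x)) {
    below <- which(y[(i0 + 1L):length(x)] < half) + i0
    if (length(below)) {
      i <- min(below)
      right <- x[i - 1L] + (x[i] - x[i - 1L]) * (y[i - 1L] - half) / (y[i - 1L] - y[i])
    }
  }
  right - left
}

# default CLS window: peak center +/- 1.2*FWHM on each axis of `map`
.auto_cls_window <- function(map, expand = 1.2) {
  pk <- locate_extremum(map, "max")
  i0 <- .nearest_index(as.numeric(map$excitation), pk$omega1)
  j0 <- .nearest_index(as.numeric(map$emission), pk$omega3)
  fw1 <- .profile_fwhm(as.numeric(map$excitation), map$amplitude[, j0])
  fw3 <- .profile_fwhm(as.numeric(map$emission), map$amplitude[i0, ])
  list(excitation = pk$omega1 + c(-1, 1) * expand * fw1,
       emission = pk$omega3 + c(-1, 1) * expand * fw3)
}

#' Center line of a 2D peak
#'
#' For every excitation column inside the window whose maximum passes the
#' intensity threshold, returns the emission-axis location of the column
#' maximum (3-point parabolic refinement, or the intensity centroid when
#' `column_method = "centroid"`). The weight of each point is the column
#' maximum.
#'
#' @param map A `map2d`.
#' @param config A `cls_config`; `config$window` must be set (use
#'   [cls_trace()] for automatic windowing).
#' @return A data.frame with columns `omega1`, `omega3_center`, `weight`.
#' @export
center_line <- function(map, config = cls_config()) {
  stopifnot(inherits(map, "map2d"))
  window <- config$window
  if (is.null(window)) window <- .auto_cls_window(map)
  ex <- as.numeric(map$excitation); em <- as.numeric(map$emission)
  ii <- which(ex >= window$excitation[1] & ex <= window$excitation[2])
  jj <- which(em >= window$emission[1] & em <= window$emission[2])
  if (length(ii) < 3L || length(jj) < 3L) {
    stop("CLS window overlaps fewer than 3 x 3 pixels")
  }
  slice_max <- max(map$amplitude[ii, jj])
  out <- list()
  for (i in ii) {
    col <- map$amplitude[i, jj]
    cmax <- max(col)
    if (cmax < config$min_rel_intensity * slice_max) next
    if (config$column_method == "parabolic") {
      j_local <- which.max(col)
      ref <- .parabolic_refine(em[jj], col, j_local)
      center <- ref$x
    } else {
      w <- pmax(col, 0)
      if (sum(w) <= 0) next
      center <- sum(em[jj] * w) / sum(w)
    }
    out[[length(out) + 1L]] <- c(ex[i], center, cmax)
  }
  if (length(out) < 3L) {
    stop("fewer than 3 usable columns in the CLS window (",
         length(out), " passed the intensity threshold)")
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("omega1", "omega3_center", "weight")
  df
}

#' Center line slope of one 2D map
#'
#' Weighted least-squares slope of the center line (emission-axis column
#' maxima versus excitation frequency). For a bivariate Gaussian peak this
#' equals `rho * sigma3 / sigma1`, the normalized frequency-frequency
#' correlation, so tracking it versus population time measures spectral
#' diffusion.
#'
#' @param map A `map2d`.
#' @param config A `cls_config`.
#' @return The slope (dimensionless).
#' @export
cls_value <- function(map, config = cls_config()) {
  cl <- center_line(map, config)
  w <- if (config$weighted) cl$weight else rep(1, nrow(cl))
  x <- cl$omega1; y <- cl$omega3_center
  xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= .Machine$double.eps * sum(w) * max(x^2)) {
    stop("degenerate excitation spread in the center line")
  }
  sum(w * (x - xb) * (y - yb)) / sxx
}

#' Center line slope versus population time
#'
#' Applies [cls_value()] to every t2 slice using a common window (the user's
#' window, or one derived from the t2 = 0 slice). Slices where the center
#' line cannot be formed are dropped from the trace.
#'
#' @param ds A `dataset_2des`.
#' @param config A `cls_config`.
#' @return A data.frame of class `"cls_trace"` with columns `t2_fs`, `slope`,
#'   `n_columns`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(get_preset("rt_lineshape"))
#' tr <- cls_trace(ds)
#' head(tr)
#' }
#' @export
cls_trace <- function(ds, config = cls_config()) {
  stopifnot(inherits(ds, "dataset_2des"))
  if (is.null(config$window)) {
    config$window <- .auto_cls_window(slice_map(ds, as.numeric(ds$time)[1]))
  }
  t2 <- as.numeric(ds$time)
  rows <- list()
  for (k in seq_along(t2)) {
    m <- map2d(ds$excitation, ds$emission, ds$cube[, , k])
    res <- tryCatch({
      cl <- center_line(m, config)
      c(cls_value(m, config), nrow(cl))
    }, error = function(e) NULL)
    if (is.null(res)) next
    if (!is.finite(res[1]) || abs(res[1]) > 2) next  # sanity bound on slopes
    rows[[length(rows) + 1L]] <- c(t2[k], res)
  }
  if (!length(rows)) stop("CLS failed on every slice")
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("t2_fs", "slope", "n_columns")
  class(df) <- c("cls_trace", "data.frame")
  df
}

#' Exponential fit of a CLS trace
#'
#' Fits `slope(t2) = a * exp(-t2 / tau) + b` by nonlinear least squares with
#' a deterministic multistart over tau (log-spaced across the t2 span; for
#' each candidate the amplitude and asymptote are solved linearly, then the
#' best candidate is refined with Levenberg-Marquardt). The decay constant is
#' the spectral-diffusion time. A trace without appreciable decay is
#' reported with `tau_identifiable = FALSE` (rule: |a| <= 3 x fit RMSE), the
#' asymptote `b` then carrying the level.
#'
#' @param trace A `cls_trace` (needs at least 5 usable points).
#' @return A list of class `"cls_fit"`: `tau` (fs), `a`, `b`, `rmse`,
#'   `tau_identifiable`.
#' @export
fit_cls_exponential <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("t2_fs", "slope") %in% names(trace)))
  t2 <- trace$t2_fs; y <- trace$slope
  ok <- is.finite(t2) & is.finite(y)
  t2 <- t2[ok]; y <- y[ok]
  if (length(t2) < 5L) stop("need at least 5 usable CLS points, got ", length(t2))
  span <- max(t2) - min(t2)

  # multistart: solve (a, b) linearly for each candidate tau
  taus <- exp(seq(log(span / 200), log(5 * span), length.out = 25))
  screen <- vapply(taus, function(tau) {
    X <- cbind(exp(-t2 / tau), 1)
    fit <- stats::lm.fit(X, y)
    c(sum(fit$residuals^2), fit$coefficients)
  }, numeric(3))
  best <- which.min(screen[1, ])
  start <- list(a = unname(screen[2, best]), tau = taus[best],
                b = unname(screen[3, best]))

  refined <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t2 / tau) + b, start = start,
                      lower = c(a = -Inf, tau = span / 1e4, b = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(refined)) {
    cf <- stats::coef(refined)
    a <- cf[["a"]]; tau <- cf[["tau"]]; b <- cf[["b"]]
    rss <- sum(stats::resid(refined)^2)
  } else {
    a <- start$a; tau <- start$tau; b <- start$b
    rss <- screen[1, best]
  }
  rmse <- sqrt(rss / length(t2))
  structure(list(tau = tau, a = a, b = b, rmse = rmse,
                 tau_identifiable = abs(a) > 3 * rmse + 1e-12),
            class = "cls_fit")
}

#' @export
print.cls_fit <- function(x, ...) {
  cat(sprintf("<cls_fit> slope(t2) = %.4g * exp(-t2 / %.4g fs) + %.4g  (rmse %.3g)\n",
              x$a, x$tau, x$b, x$rmse))
  if (!x$tau_identifiable) {
    cat("  decay amplitude is within the noise: tau not identifiable,",
        "the asymptote b carries the level\n")
  }
  invisible(x)
}
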