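#' Configuration of the multi-exponential global fit
#'
#' @param n_exp Number of exponential components (default 2, the standard
#'   bi-exponential description of sub-ps chlorophyll kinetics).
#' @param t2_min Fit-window start, fs (default 10): the earliest population
#'   times are excluded to avoid pulse-overlap artifacts.
#' @param tau_bounds Allowed decay-constant range (fs, fs); default 20 fs to
#'   50 ps.
#' @param n_starts Number of multistart initial tau tuples, log-spaced across
#'   `tau_bounds` (default 8).
#' @param include_offset Include a non-decaying offset column (default TRUE).
#' @param tol Relative SSR convergence tolerance of the simplex refinement
#'   (default 1e-10).
#' @return A list of class `"global_fit_config"`.
#' @export
global_fit_config <- function(n_exp = 2L, t2_min = 10, tau_bounds = c(20, 50000),
                              n_starts = 8L, include_offset = TRUE,
                              tol = 1e-10) {
  n_exp <- as.integer(n_exp)
  if (is.na(n_exp) || n_exp < 1L) stop("n_exp must be >= 1")
  if (t2_min < 0) stop("t2_min must be >= 0")
  if (length(tau_bounds) != 2L || tau_bounds[1] <= 0 ||
      tau_bounds[1] >= tau_bounds[2]) {
    stop("tau_bounds must be (lo, hi) with 0 < lo < hi")
  }
  structure(list(n_exp = n_exp, t2_min = t2_min,
                 tau_bounds = as.numeric(tau_bounds),
                 n_starts = as.integer(n_starts),
                 include_offset = isTRUE(include_offset), tol = tol),
            class = "global_fit_config")
}

#' Exponential design matrix
#'
#' Column j is `exp(-t2 / tau_j)`; if `include_offset` an all-ones column is
#' appended. This is the linear part of the variable-projection model.
#'
#' @param taus Decay constants, fs, all positive.
#' @param time A `time_axis` (or numeric vector of times, fs).
#' @param include_offset Append a constant column (default TRUE).
#' @return Numeric matrix, `length(time)` x `(length(taus) + include_offset)`.
#' @export
design_matrix <- function(taus, time, include_offset = TRUE) {
  taus <- as.numeric(taus)
  if (any(!is.finite(taus)) || any(taus <= 0)) stop("taus must be positive")
  t2 <- as.numeric(time)
  X <- vapply(taus, function(tau) exp(-t2 / tau), numeric(length(t2)))
  X <- matrix(X, nrow = length(t2))
  if (include_offset) X <- cbind(X, 1)
  X
}

# flatten the cube to a (time x pixel) matrix restricted to t2 >= t2_min
.fit_window <- function(ds, t2_min) {
  t2 <- as.numeric(ds$time)
  keep <- which(t2 >= t2_min)
  d <- dim(ds$cube)
  Y <- t(matrix(ds$cube, d[1] * d[2], d[3]))[keep, , drop = FALSE]
  list(Y = Y, t2 = t2[keep], keep = keep, n1 = d[1], n3 = d[2])
}

#' Solve the per-pixel amplitudes for fixed decay constants
#'
#' Ordinary linear least squares of every pixel's trace (for t2 >= t2_min)
#' against the exponential design matrix — the inner, exactly solvable step
#' of variable projection. All pixels share the decay constants; their
#' amplitudes form the 2D decay-associated spectra.
#'
#' @param ds A `dataset_2des`.
#' @param taus Decay constants, fs, strictly distinct.
#' @param config A `global_fit_config` (only `t2_min` and `include_offset`
#'   are used here).
#' @return List with `das` (list of `map2d`, one per tau), `offset` (`map2d`
#'   or NULL), and `ssr` (total sum of squared residuals over all pixels).
#' @export
solve_amplitudes <- function(ds, taus, config = global_fit_config()) {
  stopifnot(inherits(ds, "dataset_2des"))
  taus <- as.numeric(taus)
  if (any(duplicated(signif(log(taus), 8)))) {
    stop("duplicate decay constants give a rank-deficient design matrix")
  }
  w <- .fit_window(ds, config$t2_min)
  if (length(w$t2) < length(taus) + 2L) {
    stop("fit window holds ", length(w$t2), " time points; need at least ",
         length(taus) + 2L)
  }
  X <- design_matrix(taus, w$t2, config$include_offset)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient for taus ",
                               paste(format(taus), collapse = ", "))
  coefs <- qr.coef(qrX, w$Y)
  resid <- w$Y - X %*% coefs
  das <- lapply(seq_along(taus), function(j) {
    map2d(ds$excitation, ds$emission, matrix(coefs[j, ], w$n1, w$n3))
  })
  offset <- if (config$include_offset) {
    map2d(ds$excitation, ds$emission, matrix(coefs[nrow(coefs), ], w$n1, w$n3))
  } else NULL
  list(das = das, offset = offset, ssr = sum(resid^2))
}

# projected SSR for log-taus; infinite outside bounds or for coincident taus
.varpro_ssr <- function(log_taus, Y, t2, sum_y2, config) {
  lb <- log(config$tau_bounds[1]); ub <- log(config$tau_bounds[2])
  pen <- sum(pmax(0, lb - log_taus)^2 + pmax(0, log_taus - ub)^2)
  lt <- sort(pmin(pmax(log_taus, lb), ub))
  sep <- if (length(lt) > 1L) min(diff(lt)) else Inf
  if (sep < 0.01) pen <- pen + (0.01 - sep)^2
  X <- design_matrix(exp(lt), t2, config$include_offset)
  Q <- qr.Q(qr(X))
  ssr <- sum_y2 - sum(crossprod(Q, Y)^2)
  ssr * (1 + 1e3 * pen) + sum_y2 * 1e3 * pen
}

#' Multi-exponential global fit by variable projection
#'
#' Fits `cube(omega1, omega3, t2) = sum_k DAS_k * exp(-t2 / tau_k) + offset`
#' with the decay constants shared by all pixels. The per-pixel amplitudes
#' are eliminated exactly by linear least squares ([solve_amplitudes()]), so
#' the nonlinear search runs only over the log decay constants. The search
#' uses `n_starts` deterministic log-spaced starting tuples followed by
#' Nelder-Mead refinement; the result is the lowest-SSR minimum (ties broken
#' by the smaller fast constant), so the fit is deterministic for a given
#' dataset and configuration.
#'
#' @param ds A `dataset_2des`.
#' @param config A `global_fit_config`.
#' @return A `global_fit_result`: list with `taus` (ascending, fs), `das`
#'   (list of `map2d` matched to `taus`), `offset` (`map2d` or NULL), `ssr`,
#'   `labels` (human-readable constants, with values >= 1000 fs reported as
#'   ">1 ps"), and `config`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(get_preset("rt_kinetic"))
#' fit <- fit_global(ds, global_fit_config(n_exp = 2))
#' fit$taus
#' }
#' @export
fit_global <- function(ds, config = global_fit_config()) {
  stopifnot(inherits(ds, "dataset_2des"), inherits(config, "global_fit_config"))
  w <- .fit_window(ds, config$t2_min)
  if (length(w$t2) < config$n_exp + 2L) {
    stop("fit window holds ", length(w$t2), " time points; need at least ",
         config$n_exp + 2L, " for ", config$n_exp, " exponentials")
  }
  sum_y2 <- sum(w$Y^2)
  lb <- log(config$tau_bounds[1]); ub <- log(config$tau_bounds[2])

  # deterministic multistart: geometric anchor ladder, components an octave
  # ladder above each anchor, clamped inside the bounds
  spread <- min(log(8), (ub - lb) / max(config$n_exp, 1))
  anchors <- seq(lb + 0.1 * (ub - lb), ub - 0.1 * (ub - lb),
                 length.out = max(config$n_starts, 1L))
  starts <- lapply(anchors, function(a) {
    pmin(pmax(a + spread * (0:(config$n_exp - 1L)), lb + 1e-3), ub - 1e-3)
  })

  best <- NULL
  for (s in starts) {
    fit <- if (config$n_exp == 1L) {
      opt <- stats::optimize(function(u) .varpro_ssr(u, w$Y, w$t2, sum_y2, config),
                             interval = c(lb, ub), tol = 1e-10)
      list(par = opt$minimum, value = opt$objective, convergence = 0L)
    } else {
      fit0 <- stats::optim(s, .varpro_ssr, Y = w$Y, t2 = w$t2, sum_y2 = sum_y2,
                           config = config, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = config$tol))
      # restart the simplex at the optimum: a standard polish step that
      # guards against premature simplex collapse in >= 2 dimensions
      stats::optim(fit0$par, .varpro_ssr, Y = w$Y, t2 = w$t2, sum_y2 = sum_y2,
                   config = config, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = config$tol))
    }
    taus <- sort(exp(pmin(pmax(fit$par, lb), ub)))
    cand <- list(taus = taus, ssr = fit$value, convergence = fit$convergence)
    if (is.null(best) || cand$ssr < best$ssr * (1 - 1e-12) ||
        (abs(cand$ssr - best$ssr) <= best$ssr * 1e-12 &&
         cand$taus[1] < best$taus[1])) {
      best <- cand
    }
  }
  if (is.null(best) || !is.finite(best$ssr)) {
    stop("global fit did not converge from any start; best SSR: ",
         if (is.null(best)) "none" else format(best$ssr))
  }
  amp <- solve_amplitudes(ds, best$taus, config)
  structure(list(taus = best$taus, das = amp$das, offset = amp$offset,
                 ssr = amp$ssr, labels = format_tau_labels(best$taus),
                 config = config),
            class = "global_fit_result")
}

#' Human-readable decay-constant labels
#'
#' Constants of at least 1000 fs are reported as ">1 ps" (their numeric value
#' is retained in `taus`); faster constants are printed in fs.
#'
#' @param taus Decay constants, fs.
#' @return Character vector of labels.
#' @export
format_tau_labels <- function(taus) {
  ifelse(taus >= 1000, ">1 ps", sprintf("%.0f fs", taus))
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat("<global_fit_result>\n")
  for (j in seq_along(x$taus)) {
    cat(sprintf("  component %d: tau = %.4g fs (%s)\n",
                j, x$taus[j], x$labels[j]))
  }
  cat(sprintf("  offset: %s;  total SSR = %.6g\n",
              if (is.null(x$offset)) "none" else "included", x$ssr))
  invisible(x)
}

#' Reconstruct a dataset from a global-fit result
#'
#' Evaluates `sum_k DAS_k * exp(-t2 / tau_k) + offset` on the given time
#' axis.
#'
#' @param result A `global_fit_result`.
#' @param time A `time_axis` (or numeric vector, fs).
#' @return A `dataset_2des` of the modeled signal.
#' @export
reconstruct <- function(result, time) {
  stopifnot(inherits(result, "global_fit_result"))
  if (!inherits(time, "time_axis")) time <- time_axis(time)
  t2 <- as.numeric(time)
  ex <- result$das[[1]]$excitation; em <- result$das[[1]]$emission
  cube <- array(0, dim = c(length(ex), length(em), length(t2)))
  for (j in seq_along(result$taus)) {
    cube <- cube + outer(result$das[[j]]$amplitude, exp(-t2 / result$taus[j]))
  }
  if (!is.null(result$offset)) {
    cube <- cube + outer(result$offset$amplitude, rep(1, length(t2)))
  }
  dataset_2des(ex, em, time, cube, meta = list(reconstruction = TRUE))
}

#' Oscillating residues after subtracting the fitted kinetics
#'
#' Returns `ds - reconstruct(result)` restricted to the fit window
#' `t2 >= t2_min`: the part of the signal not captured by the
#' multi-exponential population kinetics, i.e. the coherent beats plus noise.
#'
#' @param ds The `dataset_2des` the fit was computed on.
#' @param result The `global_fit_result`.
#' @return A `dataset_2des` of residues on the truncated time axis.
#' @export
residues <- function(ds, result) {
  stopifnot(inherits(ds, "dataset_2des"), inherits(result, "global_fit_result"))
  if (!all(dim(result$das[[1]]$amplitude) ==
           c(length(ds$excitation), length(ds$emission)))) {
    stop("fit result shape does not match the dataset")
  }
  t2 <- as.numeric(ds$time)
  keep <- which(t2 >= result$config$t2_min)
  tw <- time_axis(t2[keep])
  model <- reconstruct(result, tw)
  dataset_2des(ds$excitation, ds$emission, tw,
               ds$cube[, , keep, drop = FALSE] - model$cube,
               meta = c(ds$meta, list(residues = TRUE)))
}
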