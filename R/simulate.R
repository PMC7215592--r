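#' Bivariate Gaussian feature of a 2D spectrum
#'
#' Describes one spectral feature as a (possibly correlated) 2D Gaussian in
#' excitation-emission frequency space. A positive excitation-emission
#' correlation `rho` elongates the feature along the diagonal, the signature
#' of inhomogeneous broadening before spectral diffusion.
#'
#' @param center Numeric length-2, (omega1, omega3) center, cm^-1.
#' @param sigma1,sigma3 Marginal standard deviations along excitation and
#'   emission, cm^-1, > 0.
#' @param rho Excitation-emission correlation, |rho| < 1.
#' @param amplitude Signed peak amplitude (value at the center).
#' @return A list of class `"gaussian2d_feature"`.
#' @export
gaussian2d_feature <- function(center, sigma1, sigma3, rho, amplitude) {
  center <- as.numeric(center)
  if (length(center) != 2L || any(!is.finite(center))) {
    stop("center must be a finite (omega1, omega3) pair")
  }
  if (sigma1 <= 0 || sigma3 <= 0) stop("sigma1 and sigma3 must be positive")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  structure(list(center = center, sigma1 = sigma1, sigma3 = sigma3,
                 rho = rho, amplitude = amplitude),
            class = "gaussian2d_feature")
}

#' Render a Gaussian feature on a frequency grid
#'
#' Evaluates `amplitude * exp(-z/2)` where `z` is the standard bivariate
#' Gaussian quadratic form in the scaled, correlated coordinates; the value
#' at the center equals `amplitude`.
#'
#' @param f A `gaussian2d_feature`.
#' @param excitation,emission Frequency axes, cm^-1.
#' @return A `map2d`.
#' @export
render_feature <- function(f, excitation, emission) {
  stopifnot(inherits(f, "gaussian2d_feature"))
  ex <- as.numeric(excitation); em <- as.numeric(emission)
  u <- (ex - f$center[1]) / f$sigma1
  v <- (em - f$center[2]) / f$sigma3
  z <- (outer(u^2, rep(1, length(v))) + outer(rep(1, length(u)), v^2) -
          2 * f$rho * outer(u, v)) / (1 - f$rho^2)
  map2d(excitation, emission, f$amplitude * exp(-z / 2))
}

# sum of rendered features as a plain matrix
.render_features <- function(features, excitation, emission) {
  acc <- matrix(0, length(excitation), length(emission))
  for (f in features) {
    acc <- acc + render_feature(f, excitation, emission)$amplitude
  }
  acc
}

#' Kinetic component: one decay constant and its decay-associated spectrum
#'
#' @param tau Decay constant in fs (> 0), or the string `"offset"` for a
#'   non-decaying component.
#' @param features List of `gaussian2d_feature`s whose sum is the component's
#'   2D decay-associated spectrum (2D-DAS).
#' @return A list of class `"kinetic_component"`.
#' @export
kinetic_component <- function(tau, features) {
  if (!identical(tau, "offset")) {
    tau <- as.numeric(tau)
    if (!is.finite(tau) || tau <= 0) stop("tau must be > 0 fs or \"offset\"")
  }
  stopifnot(is.list(features),
            all(vapply(features, inherits, TRUE, "gaussian2d_feature")))
  structure(list(tau = tau, features = features), class = "kinetic_component")
}

#' Spectral-diffusion lineshape model
#'
#' A single diagonal peak whose excitation-emission correlation relaxes as
#' `rho(t2) = rho_inf + (rho0 - rho_inf) * exp(-t2 / tau_sd)` while the
#' overall amplitude decays as `exp(-t2 / tau_amp)`. This is the minimal
#' phenomenology of spectral diffusion: a diagonally elongated peak that
#' becomes round as the environment loses memory of the excitation frequency.
#'
#' @param center (omega1, omega3) peak center, cm^-1.
#' @param sigma1,sigma3 Marginal widths, cm^-1.
#' @param rho0 Initial correlation, `rho_inf <= rho0 < 1`.
#' @param rho_inf Asymptotic correlation, `0 <= rho_inf`.
#' @param tau_sd Spectral-diffusion time constant, fs, > 0.
#' @param tau_amp Overall amplitude decay constant, fs, > 0.
#' @return A list of class `"lineshape_model"`.
#' @export
lineshape_model <- function(center, sigma1, sigma3, rho0, rho_inf, tau_sd, tau_amp) {
  if (!(rho_inf >= 0 && rho_inf <= rho0 && rho0 < 1)) {
    stop("require 0 <= rho_inf <= rho0 < 1")
  }
  if (tau_sd <= 0 || tau_amp <= 0) stop("tau_sd and tau_amp must be positive")
  structure(list(center = as.numeric(center), sigma1 = sigma1, sigma3 = sigma3,
                 rho0 = rho0, rho_inf = rho_inf,
                 tau_sd = tau_sd, tau_amp = tau_amp),
            class = "lineshape_model")
}

#' Damped vibrational beat mode
#'
#' One vibrational coherence: a damped cosine along t2 at wavenumber `nu`,
#' spatially localized by a Gaussian profile, with amplitude expressed as a
#' fraction of the dataset maximum.
#'
#' @param nu Mode wavenumber, cm^-1, > 0 and below the t2 Nyquist frequency
#'   of the dataset it is added to.
#' @param amplitude Beat amplitude as a fraction of `max(abs(cube))`, >= 0.
#' @param damping Exponential damping time, fs, > 0.
#' @param phase Phase at t2 = 0, rad.
#' @param profile `gaussian2d_feature` giving the spatial localization.
#' @return A list of class `"beat_mode"`.
#' @export
beat_mode <- function(nu, amplitude, damping, phase = 0, profile) {
  if (nu <= 0) stop("nu must be positive")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (damping <= 0) stop("damping must be positive")
  stopifnot(inherits(profile, "gaussian2d_feature"))
  structure(list(nu = nu, amplitude = amplitude, damping = damping,
                 phase = phase, profile = profile),
            class = "beat_mode")
}

#' Additive-noise specification
#'
#' @param sigma_rel Gaussian noise standard deviation as a fraction of the
#'   dataset maximum absolute value, >= 0.
#' @param seed Integer RNG seed; identical seeds give bit-identical noise.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(sigma_rel, seed = 2836L) {
  if (sigma_rel < 0) stop("sigma_rel must be >= 0")
  structure(list(sigma_rel = sigma_rel, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Build the simulation grid
#'
#' Identical excitation and emission axes of `n_omega` uniform points between
#' `omega_min` and `omega_max`, and a population-time axis 0, dt2, ...,
#' up to (at most) `t2_max`.
#'
#' @param omega_min,omega_max Frequency range, cm^-1, `omega_max > omega_min`.
#' @param n_omega Number of frequency points per axis, >= 8.
#' @param t2_max Latest population time, fs.
#' @param dt2 Population-time step, fs, > 0.
#' @return List with `excitation`, `emission` (`frequency_axis`) and `time`
#'   (`time_axis`).
#' @examples
#' g <- make_grid(13800, 17600, 96, 1000, 7.5)
#' length(g$time) # 134 points, 0 to 997.5 fs
#' @export
make_grid <- function(omega_min, omega_max, n_omega, t2_max, dt2) {
  if (omega_max <= omega_min) stop("omega_max must exceed omega_min")
  if (n_omega < 8L) stop("n_omega must be >= 8")
  if (dt2 <= 0) stop("dt2 must be positive")
  freq <- seq(omega_min, omega_max, length.out = n_omega)
  n_t <- floor(t2_max / dt2 + 1e-9) + 1L
  t2 <- seq(0, by = dt2, length.out = max(n_t, 1L))
  list(excitation = frequency_axis(freq),
       emission = frequency_axis(freq),
       time = if (length(t2) >= 2L) time_axis(t2) else structure(t2, class = "time_axis"))
}

#' Simulation preset
#'
#' Bundles a grid, a kinetic or lineshape model, beat modes, and a noise
#' specification; see [get_preset()] for the presets shipped with the
#' package.
#'
#' @param name Preset name.
#' @param grid Named list `(omega_min, omega_max, n_omega, t2_max, dt2)`.
#' @param mode `"kinetic"` or `"lineshape"`.
#' @param components List of `kinetic_component`s (kinetic mode only).
#' @param lineshape A `lineshape_model` (lineshape mode only).
#' @param beats List of `beat_mode`s (possibly empty).
#' @param noise A `noise_spec`.
#' @param temperature Free-text temperature label for metadata.
#' @return A list of class `"preset_2des"`.
#' @export
preset_2des <- function(name, grid, mode = c("kinetic", "lineshape"),
                        components = NULL, lineshape = NULL,
                        beats = list(), noise = noise_spec(0),
                        temperature = "") {
  mode <- match.arg(mode)
  if (mode == "kinetic") {
    if (is.null(components) || !is.null(lineshape)) {
      stop("kinetic mode requires components and no lineshape")
    }
  } else {
    if (is.null(lineshape) || !is.null(components)) {
      stop("lineshape mode requires a lineshape model and no components")
    }
  }
  structure(list(name = name, grid = grid, mode = mode,
                 components = components, lineshape = lineshape,
                 beats = beats, noise = noise, temperature = temperature),
            class = "preset_2des")
}

#' Generate a dataset from a kinetic preset
#'
#' Builds `cube(omega1, omega3, t2) = sum_k DAS_k(omega1, omega3) *
#' exp(-t2 / tau_k) + offset(omega1, omega3)`, where each 2D-DAS is the sum
#' of the component's rendered Gaussian features, then applies the preset's
#' beat modes and noise.
#'
#' @param p A `preset_2des` with `mode = "kinetic"`.
#' @return A `dataset_2des`.
#' @export
generate_kinetic <- function(p) {
  stopifnot(inherits(p, "preset_2des"))
  if (p$mode != "kinetic") stop("preset mode must be \"kinetic\"")
  g <- do.call(make_grid, unname(as.list(p$grid[c("omega_min", "omega_max",
                                                  "n_omega", "t2_max", "dt2")])))
  t2 <- as.numeric(g$time)
  n1 <- length(g$excitation); n3 <- length(g$emission); nt <- length(t2)
  cube <- array(0, dim = c(n1, n3, nt))
  for (comp in p$components) {
    das <- .render_features(comp$features, g$excitation, g$emission)
    kin <- if (identical(comp$tau, "offset")) rep(1, nt) else exp(-t2 / comp$tau)
    cube <- cube + outer(das, kin)
  }
  ds <- dataset_2des(g$excitation, g$emission, g$time, cube,
                     meta = list(preset = p$name, temperature = p$temperature,
                                 seed = p$noise$seed, mode = p$mode))
  if (length(p$beats)) ds <- add_beats(ds, p$beats)
  if (p$noise$sigma_rel > 0) ds <- add_noise(ds, p$noise)
  ds
}

#' Generate a dataset from a spectral-diffusion lineshape preset
#'
#' Each t2 slice is a single bivariate Gaussian whose correlation follows
#' `rho(t2) = rho_inf + (rho0 - rho_inf) * exp(-t2 / tau_sd)` and whose peak
#' amplitude decays as `exp(-t2 / tau_amp)`; beats and noise are applied if
#' configured.
#'
#' @param p A `preset_2des` with `mode = "lineshape"`.
#' @return A `dataset_2des`.
#' @export
generate_lineshape <- function(p) {
  stopifnot(inherits(p, "preset_2des"))
  if (p$mode != "lineshape") stop("preset mode must be \"lineshape\"")
  g <- do.call(make_grid, unname(as.list(p$grid[c("omega_min", "omega_max",
                                                  "n_omega", "t2_max", "dt2")])))
  t2 <- as.numeric(g$time)
  ls <- p$lineshape
  cube <- array(0, dim = c(length(g$excitation), length(g$emission), length(t2)))
  for (k in seq_along(t2)) {
    rho_t <- ls$rho_inf + (ls$rho0 - ls$rho_inf) * exp(-t2[k] / ls$tau_sd)
    amp_t <- exp(-t2[k] / ls$tau_amp)
    f <- gaussian2d_feature(ls$center, ls$sigma1, ls$sigma3, rho_t, amp_t)
    cube[, , k] <- render_feature(f, g$excitation, g$emission)$amplitude
  }
  ds <- dataset_2des(g$excitation, g$emission, g$time, cube,
                     meta = list(preset = p$name, temperature = p$temperature,
                                 seed = p$noise$seed, mode = p$mode))
  if (length(p$beats)) ds <- add_beats(ds, p$beats)
  if (p$noise$sigma_rel > 0) ds <- add_noise(ds, p$noise)
  ds
}

#' Generate a dataset from any preset
#'
#' Dispatches to [generate_kinetic()] or [generate_lineshape()] according to
#' the preset mode.
#'
#' @param p A `preset_2des`.
#' @return A `dataset_2des`.
#' @export
generate_dataset <- function(p) {
  stopifnot(inherits(p, "preset_2des"))
  if (p$mode == "kinetic") generate_kinetic(p) else generate_lineshape(p)
}

#' Add damped vibrational beats to a dataset
#'
#' Adds, for each mode m,
#' `amplitude_m * max(abs(cube)) * profile_m(omega1, omega3) *
#' cos(2*pi*c*nu_m*t2 + phase_m) * exp(-t2 / damping_m)`.
#' Modes above the t2 Nyquist frequency are rejected.
#'
#' @param ds A `dataset_2des`.
#' @param modes List of `beat_mode`s.
#' @return The dataset with beats added.
#' @export
add_beats <- function(ds, modes) {
  stopifnot(inherits(ds, "dataset_2des"))
  if (inherits(modes, "beat_mode")) modes <- list(modes)
  t2 <- as.numeric(ds$time)
  nyquist <- 1 / (2 * axis_step(ds$time) * C_CM_PER_FS)
  scale <- max(abs(ds$cube))
  cube <- ds$cube
  for (m in modes) {
    stopifnot(inherits(m, "beat_mode"))
    if (m$nu >= nyquist) {
      stop("beat mode at ", m$nu, " cm^-1 is at or above the Nyquist frequency ",
           format(nyquist, digits = 6), " cm^-1")
    }
    if (m$amplitude == 0) next
    prof <- render_feature(m$profile, ds$excitation, ds$emission)$amplitude
    osc <- cos(2 * pi * C_CM_PER_FS * m$nu * t2 + m$phase) * exp(-t2 / m$damping)
    cube <- cube + m$amplitude * scale * outer(prof, osc)
  }
  dataset_2des(ds$excitation, ds$emission, ds$time, cube, ds$meta)
}

#' Add seeded Gaussian noise to a dataset
#'
#' Adds i.i.d. Gaussian noise with standard deviation
#' `sigma_rel * max(abs(cube))`, drawn from a generator seeded with
#' `ns$seed`. The global RNG state is saved and restored, so identical seeds
#' give bit-identical output regardless of the surrounding RNG state.
#'
#' @param ds A `dataset_2des`.
#' @param ns A `noise_spec`.
#' @return The noisy dataset.
#' @export
add_noise <- function(ds, ns) {
  stopifnot(inherits(ds, "dataset_2des"), inherits(ns, "noise_spec"))
  if (ns$sigma_rel == 0) return(ds)
  sd <- ns$sigma_rel * max(abs(ds$cube))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(ns$seed)
  noise <- array(stats::rnorm(length(ds$cube), sd = sd), dim = dim(ds$cube))
  meta <- ds$meta
  meta$noise_sigma_rel <- ns$sigma_rel
  meta$seed <- ns$seed
  dataset_2des(ds$excitation, ds$emission, ds$time, ds$cube + noise, meta)
}
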