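# Small in-code fixtures shared across test files. Everything is generated
# programmatically; grids are kept small so the full suite stays fast.

# compact frequency axes around the chlorophyll Qy region
small_axes <- function(n = 48, lo = 14000, hi = 17000) {
  frequency_axis(seq(lo, hi, length.out = n))
}

# single-exponential dataset with a Gaussian DAS, optionally with offset map
single_exp_dataset <- function(tau = 100, n = 24, nt = 81, dt = 12.5,
                               amp = 1, offset = 0) {
  ax <- small_axes(n)
  t2 <- time_axis(seq(0, by = dt, length.out = nt))
  das <- render_feature(gaussian2d_feature(c(15400, 15300), 350, 350, 0.3, amp),
                        ax, ax)$amplitude
  cube <- outer(das, exp(-as.numeric(t2) / tau))
  if (offset != 0) cube <- cube + offset
  dataset_2des(ax, ax, t2, cube)
}

# multi-exponential dataset from explicit components (noiseless)
multi_exp_dataset <- function(taus, n = 24, nt = 81, dt = 12.5) {
  ax <- small_axes(n)
  t2 <- time_axis(seq(0, by = dt, length.out = nt))
  cube <- array(0, dim = c(n, n, nt))
  centers <- list(c(15200, 15200), c(15800, 15400), c(14800, 16000))
  for (j in seq_along(taus)) {
    das <- render_feature(
      gaussian2d_feature(centers[[j]], 300, 300, 0, 1 / j), ax, ax)$amplitude
    cube <- cube + outer(das, exp(-as.numeric(t2) / taus[j]))
  }
  dataset_2des(ax, ax, t2, cube)
}

# residue-style dataset: damped cosine(s) on a spatial profile, no kinetics
beat_only_dataset <- function(nus, amps = rep(0.5, length(nus)),
                              damping = 600, n = 12, nt = 134, dt = 7.5,
                              uniform_profile = FALSE) {
  ax <- frequency_axis(seq(15000, 16000, length.out = n))
  t2 <- time_axis(seq(0, by = dt, length.out = nt))
  prof <- if (uniform_profile) matrix(1, n, n) else {
    render_feature(gaussian2d_feature(c(15500, 15500), 200, 200, 0, 1),
                   ax, ax)$amplitude
  }
  cube <- array(0, dim = c(n, n, nt))
  for (j in seq_along(nus)) {
    osc <- cos(2 * pi * C_CM_PER_FS * nus[j] * as.numeric(t2)) *
      exp(-as.numeric(t2) / damping)
    cube <- cube + amps[j] * outer(prof, osc)
  }
  dataset_2des(ax, ax, t2, cube)
}

# noiseless / beat-free variant of a named preset
preset_variant <- function(name, noise = TRUE, beats = TRUE, seed = NULL) {
  p <- get_preset(name)
  if (!beats) p$beats <- list()
  if (!noise) p$noise$sigma_rel <- 0
  if (!is.null(seed)) p$noise$seed <- as.integer(seed)
  p
}

# single-exponential-plus-offset fit of one trace; returns tau
fit_trace_tau <- function(trace, tau0 = 100) {
  t2 <- trace$t2_fs; y <- trace$signal
  cf <- stats::coef(minpack.lm::nlsLM(
    y ~ a * exp(-t2 / tau) + b,
    start = list(a = y[1] - y[length(y)], tau = tau0, b = y[length(y)])))
  cf[["tau"]]
}
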