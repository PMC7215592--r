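#' Built-in simulation presets
#'
#' Named parameter bundles reproducing the statistical structure of measured
#' absorptive 2DES maps of chlorophyll b at room temperature (RT) and 77 K,
#' so that the fitting, CLS and coherence stages have known recovery targets.
#'
#' All presets share the grid: excitation = emission axis of 96 points over
#' 13,800-17,600 cm^-1 and t2 from 0 to 1000 fs in 7.5 fs steps (134 points,
#' last at 997.5 fs), with 1% Gaussian noise (seed 2836).
#'
#' \describe{
#'   \item{`rt_kinetic`}{Bi-exponential kinetics at room temperature: a fast
#'     150 fs component whose 2D-DAS decays on the diagonal Qy(0,0) peak at
#'     (15,390, 15,390) cm^-1 and rises on two off-diagonal lobes (the
#'     "rounding" signature of spectral diffusion), plus a slow 3000 fs
#'     component (reported as ">1 ps") carrying the diagonal peak, a
#'     below-diagonal vibronic cross peak at (16,000, 15,250) cm^-1 and a
#'     negative excited-state-absorption dip at (15,410, 14,350) cm^-1.
#'     Nine damped vibrational beats at 200, 296, 380, 450, 530, 770, 926,
#'     1120 and 1260 cm^-1 (amplitude 3% of the dataset maximum, damping
#'     600 fs) localized on the diagonal peak.}
#'   \item{`k77_kinetic`}{Bi-exponential kinetics at 77 K: a fast 60 fs
#'     component decaying on the diagonal at (15,580, 15,580) cm^-1 and
#'     rising at below-diagonal coordinates with emission near 15,000 cm^-1
#'     and excitation maxima near 16,000 and 17,000 cm^-1 (vibrational
#'     energy redistribution), plus a slow 3000 fs component with vibronic
#'     cross peaks at excitation 15,990 and 16,400 cm^-1. The same nine beat
#'     modes, with sub-700 cm^-1 modes quenched to 0.6% amplitude (0.2x the
#'     RT value) and higher modes conserved at 3%.}
#'   \item{`rt_lineshape`}{Pure spectral diffusion at room temperature: a
#'     single diagonal peak whose excitation-emission correlation decays from
#'     0.85 to 0.05 with tau_sd = 150 fs (amplitude decay 3000 fs); no
#'     beats.}
#'   \item{`k77_lineshape`}{The frozen-solvent control: identical peak but
#'     with the correlation frozen at 0.85 (no spectral diffusion), as
#'     expected when solvent fluctuations are arrested in the glass matrix.}
#' }
#'
#' @param name One of `"rt_kinetic"`, `"k77_kinetic"`, `"rt_lineshape"`,
#'   `"k77_lineshape"`.
#' @return A `preset_2des`.
#' @examples
#' p <- get_preset("rt_lineshape")
#' p$lineshape$tau_sd
#' @export
get_preset <- function(name) {
  valid <- c("rt_kinetic", "k77_kinetic", "rt_lineshape", "k77_lineshape")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown preset ", deparse(name), "; valid presets are: ",
         paste(valid, collapse = ", "))
  }
  grid <- list(omega_min = 13800, omega_max = 17600, n_omega = 96L,
               t2_max = 1000, dt2 = 7.5)
  noise <- noise_spec(sigma_rel = 0.01, seed = 2836L)
  beat_freqs <- c(200, 296, 380, 450, 530, 770, 926, 1120, 1260)

  switch(name,
    rt_kinetic = {
      slow_diag <- gaussian2d_feature(c(15390, 15390), 300, 300, 0.5, 1.0)
      comps <- list(
        kinetic_component(150, list(
          gaussian2d_feature(c(15390, 15390), 260, 260, 0.7, 1.0),
          gaussian2d_feature(c(15150, 15700), 200, 200, 0, -0.4),
          gaussian2d_feature(c(15700, 15150), 200, 200, 0, -0.4))),
        kinetic_component(3000, list(
          slow_diag,
          gaussian2d_feature(c(16000, 15250), 220, 220, 0, 0.35),
          gaussian2d_feature(c(15410, 14350), 250, 250, 0, -0.30))))
      beats <- lapply(beat_freqs, function(nu) {
        beat_mode(nu, amplitude = 0.03, damping = 600, phase = 0,
                  profile = slow_diag)
      })
      preset_2des(name, grid, "kinetic", components = comps, beats = beats,
                  noise = noise, temperature = "RT")
    },
    k77_kinetic = {
      slow_diag <- gaussian2d_feature(c(15450, 15450), 220, 220, 0.85, 1.0)
      comps <- list(
        kinetic_component(60, list(
          gaussian2d_feature(c(15580, 15580), 200, 200, 0.85, 1.0),
          gaussian2d_feature(c(16000, 15000), 200, 200, 0, -0.5),
          gaussian2d_feature(c(17000, 15000), 200, 200, 0, -0.5))),
        kinetic_component(3000, list(
          slow_diag,
          gaussian2d_feature(c(15990, 15300), 180, 180, 0, 0.3),
          gaussian2d_feature(c(16400, 15300), 180, 180, 0, 0.3))))
      beats <- lapply(beat_freqs, function(nu) {
        beat_mode(nu, amplitude = if (nu < 700) 0.006 else 0.03,
                  damping = 600, phase = 0, profile = slow_diag)
      })
      preset_2des(name, grid, "kinetic", components = comps, beats = beats,
                  noise = noise, temperature = "77K")
    },
    rt_lineshape = preset_2des(
      name, grid, "lineshape",
      lineshape = lineshape_model(c(15390, 15390), 300, 300,
                                  rho0 = 0.85, rho_inf = 0.05,
                                  tau_sd = 150, tau_amp = 3000),
      noise = noise, temperature = "RT"),
    k77_lineshape = preset_2des(
      name, grid, "lineshape",
      lineshape = lineshape_model(c(15390, 15390), 300, 300,
                                  rho0 = 0.85, rho_inf = 0.85,
                                  tau_sd = 150, tau_amp = 3000),
      noise = noise, temperature = "77K")
  )
}
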