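test_that("make_grid builds the documented axes", {
  g <- make_grid(13800, 17600, 96, 1000, 7.5)
  expect_length(g$time, 134)                       # 0 ... 997.5 fs
  expect_equal(max(g$time), 997.5)
  expect_equal(axis_step(g$excitation), 40)
  expect_identical(as.numeric(g$excitation), as.numeric(g$emission))
  # t2_max below one step leaves the origin only
  g1 <- make_grid(13800, 17600, 16, 5, 7.5)
  expect_equal(as.numeric(g1$time), 0)
  expect_error(make_grid(17600, 13800, 96, 1000, 7.5), "exceed")
})

test_that("render_feature matches the bivariate Gaussian closed form", {
  ax <- seq(14000, 17000, length.out = 121)   # 25 cm^-1 step hits the centers
  f <- gaussian2d_feature(c(15500, 15400), 300, 200, 0, 2)
  m <- render_feature(f, ax, ax)
  i <- which.min(abs(ax - (15500 + 300))); j <- which.min(abs(ax - 15400))
  expect_equal(m$amplitude[i, j], 2 * exp(-0.5), tolerance = 1e-9)
  # grid integral ~ Gaussian normalization for a feature well inside the grid
  step <- ax[2] - ax[1]
  for (rho in c(0, 0.6, 0.9)) {
    fr <- gaussian2d_feature(c(15500, 15400), 300, 200, rho, 1.5)
    total <- sum(render_feature(fr, ax, ax)$amplitude) * step^2
    expect_equal(total, 2 * pi * 300 * 200 * sqrt(1 - rho^2) * 1.5,
                 tolerance = 1e-3)
  }
  # positive correlation elongates along the diagonal: correlated feature is
  # wider on the diagonal cut and narrower on the anti-diagonal cut
  fe <- gaussian2d_feature(c(15500, 15500), 300, 300, 0.9, 1)
  me <- render_feature(fe, ax, ax)$amplitude
  i_hi <- which.min(abs(ax - 15800)); i_lo <- which.min(abs(ax - 15200))
  expect_gt(me[i_hi, i_hi], me[i_hi, i_lo])  # same radius: diagonal beats anti-diagonal
})

test_that("kinetic generation obeys the reconstruction identity", {
  p <- preset_variant("rt_kinetic", noise = FALSE, beats = FALSE)
  ds <- generate_dataset(p)
  t2 <- as.numeric(ds$time)
  das <- lapply(p$components, function(comp) {
    Reduce(`+`, lapply(comp$features, function(f) {
      render_feature(f, ds$excitation, ds$emission)$amplitude
    }))
  })
  taus <- vapply(p$components, `[[`, numeric(1), "tau")
  for (k in c(1L, 20L, 134L)) {
    expected <- das[[1]] * exp(-t2[k] / taus[1]) + das[[2]] * exp(-t2[k] / taus[2])
    expect_equal(ds$cube[, , k], expected, tolerance = 1e-12)
  }
  # t2 = 0 slice is exactly the sum of the DAS maps
  expect_equal(ds$cube[, , 1], das[[1]] + das[[2]], tolerance = 1e-12)
})

test_that("noiseless RT diagonal trace is bi-exponential in the preset constants", {
  ds <- generate_dataset(preset_variant("rt_kinetic", noise = FALSE,
                                        beats = FALSE))
  tr <- slice_trace(ds, 15390, 15390)
  t2 <- tr$t2_fs; y <- tr$signal
  cf <- stats::coef(minpack.lm::nlsLM(
    y ~ a1 * exp(-t2 / tau1) + a2 * exp(-t2 / tau2),
    start = list(a1 = 1, tau1 = 100, a2 = 1, tau2 = 2000)))
  taus <- sort(c(cf[["tau1"]], cf[["tau2"]]))
  expect_equal(taus[1], 150, tolerance = 1e-4)
  expect_equal(taus[2], 3000, tolerance = 1e-4)
})

test_that("lineshape generation follows the correlation relaxation law", {
  p <- preset_variant("rt_lineshape", noise = FALSE)
  ds <- generate_dataset(p)
  ls <- p$lineshape
  t2 <- as.numeric(ds$time)
  ex <- as.numeric(ds$excitation); em <- as.numeric(ds$emission)
  # weighted sample correlation of each slice tracks rho(t2)
  slice_rho <- function(k) {
    w <- ds$cube[, , k]
    u <- outer(ex - ls$center[1], rep(1, length(em)))
    v <- outer(rep(1, length(ex)), em - ls$center[2])
    sw <- sum(w)
    mu <- sum(w * u) / sw; mv <- sum(w * v) / sw
    suv <- sum(w * (u - mu) * (v - mv))
    suv / sqrt(sum(w * (u - mu)^2) * sum(w * (v - mv)^2))
  }
  for (k in c(1L, 21L, 60L, 134L)) {
    rho_t <- ls$rho_inf + (ls$rho0 - ls$rho_inf) * exp(-t2[k] / ls$tau_sd)
    expect_equal(slice_rho(k), rho_t, tolerance = 0.01)
  }
  # at t2 = tau_sd the relaxing part has fallen to 1/e
  k150 <- which.min(abs(t2 - 150))
  expect_equal(slice_rho(k150),
               ls$rho_inf + (ls$rho0 - ls$rho_inf) / exp(1), tolerance = 0.01)
  # frozen-correlation preset keeps a fixed shape: slices proportional
  dsf <- generate_dataset(preset_variant("k77_lineshape", noise = FALSE))
  s1 <- dsf$cube[, , 1] / max(dsf$cube[, , 1])
  s134 <- dsf$cube[, , 134] / max(dsf$cube[, , 134])
  expect_equal(s1, s134, tolerance = 1e-10)
})

test_that("beats oscillate at the requested wavenumber and respect Nyquist", {
  ds <- single_exp_dataset(tau = 1e9, n = 24, nt = 134, dt = 7.5)  # ~static
  prof <- gaussian2d_feature(c(15400, 15300), 350, 350, 0, 1)
  m770 <- beat_mode(770, 0.2, damping = 1e9, phase = 0, profile = prof)
  with_beat <- add_beats(ds, list(m770))
  osc <- slice_trace(with_beat, 15400, 15300)$signal -
    slice_trace(ds, 15400, 15300)$signal
  # period 1/(c * 770) ~ 43.3 fs: autocorrelation peaks near lag 6 samples
  period <- 1 / (C_CM_PER_FS * 770)
  expect_equal(period, 43.3, tolerance = 1e-3)
  spec_bin <- which.max(Mod(stats::fft(osc))[2:67])
  freq <- fft_wavenumber_axis(7.5, 134)[-1][spec_bin]
  expect_lt(abs(freq - 770), 33.2)          # within one unpadded bin
  # zero-amplitude mode is the identity
  expect_identical(add_beats(ds, list(beat_mode(500, 0, 600, 0, prof)))$cube,
                   ds$cube)
  expect_error(add_beats(ds, list(beat_mode(2500, 0.1, 600, 0, prof))),
               "Nyquist")
})

test_that("seeded noise is reproducible and correctly scaled", {
  ds <- generate_dataset(preset_variant("rt_lineshape", noise = FALSE))
  ns <- noise_spec(0.01, seed = 77)
  noisy1 <- add_noise(ds, ns)
  noisy2 <- add_noise(ds, ns)
  expect_identical(noisy1$cube, noisy2$cube)
  expect_false(identical(add_noise(ds, noise_spec(0.01, seed = 78))$cube,
                         noisy1$cube))
  # ~1.2M samples: the realized s.d. is within 2% of the nominal one
  realized <- stats::sd(noisy1$cube - ds$cube)
  expect_equal(realized, 0.01 * max(abs(ds$cube)), tolerance = 0.02)
  # sigma_rel = 0 is the identity
  expect_identical(add_noise(ds, noise_spec(0))$cube, ds$cube)
})

test_that("generator is linear in the feature amplitudes", {
  p <- preset_variant("rt_kinetic", noise = FALSE, beats = FALSE)
  p$grid$n_omega <- 24L; p$grid$t2_max <- 300
  ds1 <- generate_dataset(p)
  p3 <- p
  p3$components <- lapply(p$components, function(comp) {
    comp$features <- lapply(comp$features, function(f) { f$amplitude <- 3 * f$amplitude; f })
    comp
  })
  ds3 <- generate_dataset(p3)
  expect_equal(ds3$cube, 3 * ds1$cube, tolerance = 1e-14)
})

test_that("full presets are bit-reproducible and carry the documented constants", {
  expect_error(get_preset("nope"), "rt_kinetic")
  rt <- get_preset("rt_kinetic")
  expect_equal(rt$components[[1]]$tau, 150)
  expect_equal(rt$components[[2]]$tau, 3000)
  expect_equal(vapply(rt$beats, `[[`, numeric(1), "nu"),
               c(200, 296, 380, 450, 530, 770, 926, 1120, 1260))
  k77 <- get_preset("k77_kinetic")
  expect_equal(k77$components[[1]]$tau, 60)
  amps <- vapply(k77$beats, `[[`, numeric(1), "amplitude")
  nus <- vapply(k77$beats, `[[`, numeric(1), "nu")
  expect_true(all(amps[nus < 700] == 0.006) && all(amps[nus >= 700] == 0.03))
  expect_equal(get_preset("rt_lineshape")$lineshape$tau_sd, 150)
  kls <- get_preset("k77_lineshape")$lineshape
  expect_identical(kls$rho0, kls$rho_inf)
  # identical preset + seed => bit-identical dataset
  a <- generate_dataset(get_preset("rt_kinetic"))
  b <- generate_dataset(get_preset("rt_kinetic"))
  expect_identical(a$cube, b$cube)
})
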