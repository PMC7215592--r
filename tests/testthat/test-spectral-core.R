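test_that("wavelength/wavenumber conversion matches closed form and round-trips", {
  expect_equal(wavelength_nm_to_wavenumber(1000), 10000)
  expect_equal(wavelength_nm_to_wavenumber(500), 20000)
  expect_equal(wavelength_nm_to_wavenumber(650), 15384.6154, tolerance = 1e-8)
  expect_error(wavelength_nm_to_wavenumber(0), "positive")
  expect_error(wavenumber_to_wavelength_nm(-5), "positive")
  for (lambda in c(1, 213.7, 650, 1e4)) {
    expect_equal(wavenumber_to_wavelength_nm(wavelength_nm_to_wavenumber(lambda)),
                 lambda, tolerance = 1e-10)
  }
})

test_that("transform-limited Gaussian bandwidth reproduces the 10 fs benchmark", {
  # a 10 fs intensity-FWHM pulse spans about 1471 cm^-1
  expect_equal(transform_limited_gaussian_bandwidth(10), 1471, tolerance = 1e-3)
  expect_equal(transform_limited_gaussian_bandwidth(20),
               transform_limited_gaussian_bandwidth(10) / 2)
  # closed form at 100 fs: K / (dt * c)
  expect_equal(transform_limited_gaussian_bandwidth(100),
               0.44127 / (100 * 2.99792458e-5), tolerance = 1e-4)
  dts <- c(5, 10, 25, 80, 300)
  expect_true(all(diff(transform_limited_gaussian_bandwidth(dts)) < 0))
  expect_error(transform_limited_gaussian_bandwidth(-1), "positive")
})

test_that("FFT wavenumber axis has the right span, spacing and padding behaviour", {
  ax <- fft_wavenumber_axis(7.5, 134, 1)
  expect_equal(max(ax), 1 / (2 * 7.5 * C_CM_PER_FS))     # Nyquist ~ 2224
  expect_equal(max(ax), 2223.9, tolerance = 1e-4)
  expect_equal(axis_step(ax), 1 / (134 * 7.5 * C_CM_PER_FS))
  expect_equal(axis_step(ax), 33.19, tolerance = 1e-3)
  ax4 <- fft_wavenumber_axis(7.5, 134, 4)
  expect_equal(axis_step(ax4), axis_step(ax) / 4)
  # exact reciprocal identity, up to float epsilon
  for (n in c(16, 100, 134)) {
    for (pf in c(1L, 3L)) {
      a <- fft_wavenumber_axis(2.5, n, pf)
      expect_equal(axis_step(a) * (n * pf * 2.5 * C_CM_PER_FS), 1,
                   tolerance = 1e-12)
    }
  }
  expect_error(fft_wavenumber_axis(-1, 10), "positive")
  expect_error(fft_wavenumber_axis(1, 1), ">= 2")
})

test_that("axis constructors enforce monotone uniform grids", {
  expect_error(frequency_axis(c(1:7)), "at least 8")
  expect_error(frequency_axis(c(1:7, 7)), "increasing")
  expect_error(frequency_axis(c(1, 2, 3, 4, 5, 6, 7, 8.5)), "uniform")
  expect_silent(time_axis(seq(0, 997.5, 7.5)))
  expect_error(time_axis(c(0, 10, 15)), "uniform")
})

test_that("locate_extremum refines sub-pixel centers and honours windows", {
  ax <- seq(14000, 17000, length.out = 76)   # 40 cm^-1 step
  # feature exactly on a grid node
  on_node <- render_feature(gaussian2d_feature(c(15400, 15200), 260, 260, 0, 1),
                            ax, ax)
  pk <- locate_extremum(on_node, "max")
  expect_equal(pk$omega1, 15400)
  expect_equal(pk$omega3, 15200)
  expect_equal(pk$value, 1, tolerance = 1e-6)
  # off-grid centers recovered within 0.1 grid step
  step <- ax[2] - ax[1]
  for (frac in c(0.15, 0.35, -0.4)) {
    ctr <- c(15400 + frac * step, 15200 - frac * step)
    m <- render_feature(gaussian2d_feature(ctr, 260, 260, 0, 1), ax, ax)
    pk <- locate_extremum(m, "max")
    expect_lt(abs(pk$omega1 - ctr[1]), 0.1 * step)
    expect_lt(abs(pk$omega3 - ctr[2]), 0.1 * step)
  }
  # negative dip found in min mode at the encoded ESA-like position
  dip <- render_feature(gaussian2d_feature(c(15410, 14350), 250, 250, 0, -0.3),
                        ax, ax)
  mn <- locate_extremum(dip, "min")
  expect_lt(abs(mn$omega1 - 15410), 0.1 * step)
  expect_lt(abs(mn$omega3 - 14350), 0.1 * step)
  expect_lt(mn$value, 0)
  # window restriction picks the secondary feature
  main <- render_feature(gaussian2d_feature(c(15400, 15600), 260, 260, 0, 1),
                         ax, ax)
  two <- map2d(ax, ax, main$amplitude + 0.5 * dip$amplitude * -1)
  pk2 <- locate_extremum(two, "max",
                         window = list(emission = c(14000, 14800)))
  expect_lt(abs(pk2$omega3 - 14350), step)
  expect_error(locate_extremum(on_node, "max",
                               window = list(excitation = c(100, 200))),
               "3 x 3")
})

test_that("locate_extremum is equivariant under axis translation", {
  ax <- seq(14000, 17000, length.out = 60)
  m <- render_feature(gaussian2d_feature(c(15417, 15213), 300, 250, 0.4, 1),
                      ax, ax)
  pk <- locate_extremum(m, "max")
  for (shift in c(-500, 123.4)) {
    m2 <- map2d(ax + shift, ax + shift, m$amplitude)
    pk2 <- locate_extremum(m2, "max")
    expect_equal(pk2$omega1, pk$omega1 + shift, tolerance = 1e-9)
    expect_equal(pk2$omega3, pk$omega3 + shift, tolerance = 1e-9)
  }
})

test_that("slice_trace uses nearest pixel with ties toward the lower index", {
  ds <- single_exp_dataset(tau = 120, n = 24)
  ex <- as.numeric(ds$excitation)
  tr <- slice_trace(ds, ex[5], ex[9])
  expect_equal(tr$signal, ds$cube[5, 9, ])
  # midway between nodes 5 and 6 -> lower index 5
  mid <- (ex[5] + ex[6]) / 2
  tr_mid <- slice_trace(ds, mid, ex[9])
  expect_equal(attr(tr_mid, "omega1"), ex[5])
  expect_error(slice_trace(ds, 1e5, ex[9]), "outside")
})

test_that("77 K kinetics: diagonal decay and cross-peak rise share the fast constant", {
  ds <- generate_dataset(preset_variant("k77_kinetic", noise = FALSE,
                                        beats = FALSE))
  diag_tr <- slice_trace(ds, 15580, 15580)
  cross_tr <- slice_trace(ds, 16000, 15000)
  expect_gt(diag_tr$signal[1], diag_tr$signal[nrow(diag_tr)])  # decays
  expect_lt(cross_tr$signal[1], max(cross_tr$signal))          # rises
  # both traces are (bi)exponential in the same constants; at the cross peak
  # the slow component is weak, so a single-exp-plus-offset fit sees ~60 fs
  expect_equal(fit_trace_tau(cross_tr, tau0 = 80), 60, tolerance = 0.1)
})
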