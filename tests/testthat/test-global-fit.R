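test_that("design matrix columns are unit at t2 = 0 and decay as specified", {
  tm <- time_axis(seq(0, 600, 75))
  X <- design_matrix(c(150, 3000), tm, include_offset = TRUE)
  expect_equal(dim(X), c(9L, 3L))
  expect_equal(X[1, ], c(1, 1, 1))
  expect_equal(X[3, 1], exp(-1))            # tau = 150 at t2 = 150
  expect_equal(X[, 3], rep(1, 9))
  # a tau at the default upper bound is ~flat over a 1 ps window
  Xf <- design_matrix(50000, time_axis(seq(0, 1000, 100)), FALSE)
  expect_true(all(Xf > 0.98))
})

test_that("solve_amplitudes recovers exact in-model amplitudes", {
  ds <- single_exp_dataset(tau = 137, offset = 0.25)
  cfg <- global_fit_config(n_exp = 1L, t2_min = 0)
  sol <- solve_amplitudes(ds, 137, cfg)
  truth <- render_feature(gaussian2d_feature(c(15400, 15300), 350, 350, 0.3, 1),
                          ds$excitation, ds$emission)$amplitude
  expect_equal(sol$das[[1]]$amplitude, truth, tolerance = 1e-9)
  expect_equal(sol$offset$amplitude, matrix(0.25, 24, 24), tolerance = 1e-9)
  expect_lt(sol$ssr, 1e-18 * sum(ds$cube^2))
  # constant dataset: exponential amplitudes vanish, offset carries the level
  dsc <- dataset_2des(ds$excitation, ds$emission, ds$time,
                      array(0.7, dim = dim(ds$cube)))
  solc <- solve_amplitudes(dsc, 137, cfg)
  expect_equal(max(abs(solc$das[[1]]$amplitude)), 0, tolerance = 1e-10)
  expect_equal(solc$offset$amplitude[1, 1], 0.7, tolerance = 1e-12)
  expect_error(solve_amplitudes(ds, c(100, 100), cfg), "rank")
})

test_that("variable projection recovers exact in-model decay constants", {
  # single component
  f1 <- fit_global(single_exp_dataset(tau = 100),
                   global_fit_config(n_exp = 1L, t2_min = 0))
  expect_equal(f1$taus, 100, tolerance = 1e-3)
  # two and three components, noiseless: taus within 0.1%, SSR ~ 0
  for (taus in list(c(150, 3000), c(80, 700, 6000))) {
    ds <- multi_exp_dataset(taus, nt = 101, dt = 10)
    fit <- fit_global(ds, global_fit_config(n_exp = length(taus), t2_min = 0))
    expect_equal(fit$taus, taus, tolerance = 1e-3)
    expect_lt(fit$ssr, 1e-12 * max(abs(ds$cube)) * length(ds$cube))
  }
})

test_that("global fit is deterministic and insensitive to the multistart count", {
  ds <- multi_exp_dataset(c(120, 2000), n = 16, nt = 61, dt = 15)
  f1 <- fit_global(ds, global_fit_config(t2_min = 0))
  f2 <- fit_global(ds, global_fit_config(t2_min = 0))
  expect_identical(f1$taus, f2$taus)
  f3 <- fit_global(ds, global_fit_config(t2_min = 0, n_starts = 4L))
  expect_equal(f3$taus, f1$taus, tolerance = 1e-4)
})

test_that("taus come back ascending with matched DAS and '>1 ps' labels", {
  ds <- multi_exp_dataset(c(2500, 90), n = 16, nt = 61, dt = 15)
  fit <- fit_global(ds, global_fit_config(t2_min = 0))
  expect_true(all(diff(fit$taus) > 0))
  expect_equal(fit$labels[2], ">1 ps")
  expect_match(fit$labels[1], "fs")
  # the DAS paired with the fast tau is the fast component's spatial pattern
  fast_das <- render_feature(gaussian2d_feature(c(15800, 15400), 300, 300, 0, 0.5),
                             ds$excitation, ds$emission)$amplitude
  expect_equal(fit$das[[1]]$amplitude, fast_das, tolerance = 1e-4)
})

test_that("reconstruction and residues are exact complements on the fit window", {
  ds <- multi_exp_dataset(c(150, 3000), nt = 81, dt = 12.5)
  fit <- fit_global(ds, global_fit_config(t2_min = 10))
  model <- reconstruct(fit, ds$time)
  expect_equal(dim(model$cube), dim(ds$cube))
  res <- residues(ds, fit)
  keep <- which(as.numeric(ds$time) >= 10)
  expect_equal(res$cube + reconstruct(fit, time_axis(as.numeric(ds$time)[keep]))$cube,
               ds$cube[, , keep], tolerance = 1e-12)
  # noiseless beat-free data: residues vanish
  expect_lt(max(abs(res$cube)), 1e-6 * max(abs(ds$cube)))
  # at large t2 the reconstruction approaches the offset map
  far <- reconstruct(fit, time_axis(c(0, 5e6)))
  expect_equal(far$cube[, , 2], fit$offset$amplitude, tolerance = 1e-6)
})

test_that("residues isolate an added beat", {
  ds <- multi_exp_dataset(c(150, 3000), nt = 101, dt = 10)
  prof <- gaussian2d_feature(c(15300, 15300), 300, 300, 0, 1)
  with_beat <- add_beats(ds, list(beat_mode(770, 0.05, 600, 0, prof)))
  fit <- fit_global(with_beat, global_fit_config(t2_min = 0))
  res <- residues(with_beat, fit)
  beat_term <- with_beat$cube - ds$cube
  # residues match the injected beat up to the kinetic misfit the beat itself
  # induces in the taus (~15% of the beat amplitude here)
  expect_lt(max(abs(res$cube - beat_term)), 0.2 * max(abs(beat_term)))
})

test_that("fast constant is stable across noise realizations on the RT preset", {
  fast <- vapply(1:10, function(s) {
    p <- preset_variant("rt_kinetic", seed = 1000 + s)
    fit_global(generate_dataset(p), global_fit_config(n_starts = 4L))$taus[1]
  }, numeric(1))
  expect_lt(stats::sd(fast) / mean(fast), 0.05)
})

test_that("fit errors are explicit for unusable windows", {
  ds <- single_exp_dataset(tau = 100, nt = 4, dt = 5)
  expect_error(fit_global(ds, global_fit_config(n_exp = 2L, t2_min = 10)),
               "time points")
})
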