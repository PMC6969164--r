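test_that("CD basis spectra place their bands at the printed positions", {
  g <- cd_grid()
  b <- gen_basis_cd("beta_sheet", g)
  expect_equal(g[which.max(b$values)], 196)
  expect_equal(g[which.min(b$values)], 218)
  u <- gen_basis_cd("unordered", g)
  expect_equal(g[which.min(u$values)], 198)
  # no positive band above 210 nm for the unordered state
  expect_true(all(u$values[g > 210] <= 1e-8))
  # deterministic: same call twice is identical
  expect_identical(gen_basis_cd("beta_sheet", g), b)
  expect_error(gen_basis_cd("beta_sheet", 200:260), "185-260")
})

test_that("CD time series is an exact two-state mixture at zero noise", {
  g <- cd_grid()
  p <- kinetic_params("logistic", k = 1, t_half = 5)
  times <- c(0, 2, 5, 8, 20)
  specs <- gen_cd_timeseries(p, times, noise_sd = 0)
  s0 <- gen_basis_cd("unordered", g)
  s1 <- gen_basis_cd("beta_sheet", g)
  y <- 1 / (1 + exp(-1 * (times - 5)))
  for (i in seq_along(times)) {
    expect_equal(specs[[i]]$values,
                 (1 - y[i]) * s0$values + y[i] * s1$values, tolerance = 1e-12)
  }
  # t = t_half gives the exact 50/50 mixture
  expect_equal(specs[[3]]$values, (s0$values + s1$values) / 2,
               tolerance = 1e-12)
  # determinism under a fixed seed
  a <- gen_cd_timeseries(p, times, noise_sd = 0.3, seed = 11)
  b <- gen_cd_timeseries(p, times, noise_sd = 0.3, seed = 11)
  expect_identical(a, b)
  expect_error(gen_cd_timeseries(p, times, noise_sd = -1), "noise_sd")
})

test_that("kinetic trace generator honours the model limits", {
  p <- kinetic_params("avrami", K = 0.1, n = 2)
  tr <- gen_kinetic_trace(p, c(0, 1, 2, 100))
  expect_equal(tr$fractions[1], 0)
  expect_equal(tr$fractions[4], 1, tolerance = 1e-12)
  expect_identical(gen_kinetic_trace(p, 0:10, 0.05, seed = 3),
                   gen_kinetic_trace(p, 0:10, 0.05, seed = 3))
})

test_that("Hertz force curve matches the closed-form forward model", {
  E <- 6e6; R <- 0.3e-6; nu <- 0.33
  fc <- gen_force_curve(E, R, nu, 100e-9, n_points = 101)
  i <- which.min(abs(fc$indentation - 1e-7))
  expect_equal(fc$force[i],
               (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * (1e-7)^1.5,
               tolerance = 1e-12)
  # adhesion-free JKR collapses onto the same curve
  fj <- gen_force_curve(E, R, nu, 100e-9, model = "jkr", work_adhesion = 0,
                        n_points = 101)
  expect_equal(fj$indentation, fc$indentation, tolerance = 1e-12)
  expect_equal(fj$force, fc$force, tolerance = 1e-12)
  expect_error(gen_force_curve(E, R, nu, 1e-7, model = "jkr"),
               "work_adhesion")
})

test_that("Amide I generator validates areas and places single bands", {
  s <- gen_amide1_spectrum(data.frame(center = 1619, fwhm = 12, area = 1))
  expect_equal(s$grid[which.max(s$values)], 1619)
  # two equal-area bands integrate equally (trapezoid, split at midpoint)
  s2 <- gen_amide1_spectrum(
    data.frame(center = c(1620, 1680), fwhm = c(10, 10), area = c(0.5, 0.5)))
  mid <- s2$grid <= 1650
  a1 <- pracma::trapz(s2$grid[mid], s2$values[mid])
  a2 <- pracma::trapz(s2$grid[!mid], s2$values[!mid])
  expect_equal(a1, a2, tolerance = 1e-6)
  expect_error(
    gen_amide1_spectrum(data.frame(center = 1619, fwhm = 12, area = 0.9)),
    "sum to 1")
})

test_that("emission generators hit the printed ANS peaks and pyrene ratio", {
  expect_equal(which.max(gen_emission_spectrum("ans_bound")$values),
               which(seq(420, 600) == 470))
  expect_equal(which.max(gen_emission_spectrum("ans_free")$values),
               which(seq(420, 600) == 520))
  ps <- gen_emission_spectrum("pyrene", i1_i3 = 2)
  expect_equal(pyrene_ratio(ps), 2, tolerance = 1e-9)
  expect_error(gen_emission_spectrum("ans_bound", grid = 430:600), "420-600")
  expect_error(gen_emission_spectrum("pyrene", grid = 360:420), "350-420")
})

test_that("scalar sample generators are seeded and parameterized correctly", {
  a <- gen_normal_sample(34, 9, 160, seed = 21)
  expect_identical(a, gen_normal_sample(34, 9, 160, seed = 21))
  expect_length(a, 160)
  b <- gen_lognormal_sample(4.18, 0.71, 5000, seed = 21)
  expect_true(all(b > 0))
  # arithmetic-moment parameterization: large-sample moments close to target
  expect_equal(mean(b), 4.18, tolerance = 0.02)
  expect_equal(sd(b), 0.71, tolerance = 0.1)
  expect_error(gen_normal_sample(1, 1, 1), "n must be")
  expect_error(gen_lognormal_sample(1, -1, 10), "sd must be")
})

test_that("gel lane generator produces a calibratable ladder and sample", {
  lanes <- gen_gel_lanes(ladder_mws(),
                         data.frame(mw = 390, amount = 1, spread = 0.02))
  cal <- calibrate_ladder(lanes$ladder, ladder_mws())
  p <- lanes$sample$positions[which.max(lanes$sample$intensities)]
  expect_equal(p, cal$position_at(390), tolerance = 1)
  # empty component list gives a flat background lane
  blank <- gen_gel_lanes(ladder_mws(), data.frame())
  expect_true(all(blank$sample$intensities == 0))
  expect_error(gen_gel_lanes(c(100, 50), data.frame()), "3 ladder bands")
})

test_that("noiseless generator output round-trips through the fitters", {
  # logistic
  for (k in c(0.05, 1, 10)) {
    tr <- gen_kinetic_trace(kinetic_params("logistic", k = k, t_half = 20),
                            seq(0, 40 + 40 / k, length.out = 60))
    f <- fit_logistic(tr)
    expect_equal(f$k, k, tolerance = 1e-6)
    expect_equal(f$t_half, 20, tolerance = 1e-6)
  }
  # avrami
  fa <- fit_avrami(gen_kinetic_trace(kinetic_params("avrami", K = 0.1, n = 2),
                                     seq(0, 30, length.out = 50)))
  expect_equal(fa$n, 2L)
  expect_equal(fa$K, 0.1, tolerance = 1e-6)
  # hertz
  fc <- gen_force_curve(6e6, 0.3e-6, 0.33, 100e-9)
  expect_equal(hertz_fit(fc), 6e6, tolerance = 1e-6)
  # pyrene ratio
  expect_equal(pyrene_ratio(gen_emission_spectrum("pyrene", i1_i3 = 1.4)),
               1.4, tolerance = 1e-6)
  # degenerate width sample
  f0 <- fit_normal(rep(19, 12))
  expect_equal(f0$mean, 19)
  expect_equal(f0$sd, 0)
})
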