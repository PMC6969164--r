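test_that("log-normal fits satisfy the moment identities", {
  x <- gen_lognormal_sample(4.18e9, 0.71e9, 500, seed = 2)
  f <- fit_lognormal(x, source = "amfm")
  expect_equal(f$mean, exp(f$mu_log + f$sigma_log^2 / 2), tolerance = 1e-12)
  expect_equal(f$sd^2,
               (exp(f$sigma_log^2) - 1) * exp(2 * f$mu_log + f$sigma_log^2),
               tolerance = 1e-12)
  # degenerate equal sample
  f0 <- fit_lognormal(rep(4.18e9, 40))
  expect_equal(f0$mean, 4.18e9)
  expect_equal(f0$sd, 0)
  # scale equivariance
  f10 <- fit_lognormal(10 * x)
  expect_equal(f10$mean, 10 * f$mean, tolerance = 1e-9)
  expect_equal(f10$sd, 10 * f$sd, tolerance = 1e-9)
  expect_error(fit_lognormal(c(x[1:29], -1)), "> 0")
})

test_that("Gaussian modulus fit recovers a seeded nanoindentation sample", {
  e <- gen_normal_sample(5.96e6, 0.48e6, 216, seed = 216)
  f <- fit_gaussian_moduli(e)
  expect_lt(abs(f$mean - 5.96e6), 3 * 0.48e6 / sqrt(216))
  expect_error(fit_gaussian_moduli(e[1:20]), "at least 30")
})

test_that("Hertz fit inverts the forward model and scales with R", {
  fc <- gen_force_curve(6e6, 0.3e-6, 0.33, 100e-9)
  expect_equal(hertz_fit(fc), 6e6, tolerance = 1e-9)
  # same data interpreted with doubled tip radius: E scales by 1/sqrt(2)
  fc2 <- force_curve(fc$indentation, fc$force, fc$segment,
                     tip_radius = 2 * fc$tip_radius, poisson = fc$poisson)
  expect_equal(hertz_fit(fc2), 6e6 / sqrt(2), tolerance = 1e-9)
  # force scaling maps linearly to modulus scaling
  fc3 <- force_curve(fc$indentation, 3 * fc$force, fc$segment,
                     fc$tip_radius, fc$poisson)
  expect_equal(hertz_fit(fc3), 3 * 6e6, tolerance = 1e-9)
})

test_that("Hertz fit tolerates noise at the documented level", {
  # median relative error over seeded 5%-noise curves stays below 5%
  errs <- vapply(1:100, function(i) {
    fc <- gen_force_curve(6e6, 0.3e-6, 0.33, 100e-9, noise_sd = 0.05 *
                            (4 / 3) * (6e6 / (1 - 0.33^2)) * sqrt(0.3e-6) *
                            (100e-9)^1.5,
                          n_points = 100, seed = 1000 + i)
    abs(hertz_fit(fc) - 6e6) / 6e6
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("JKR fit round-trips modulus and work of adhesion", {
  fj <- gen_force_curve(6.26e6, 0.3e-6, 0.33, 100e-9, model = "jkr",
                        work_adhesion = 0.05)
  # pull-off force identity of the JKR model
  expect_equal(min(fj$force), -1.5 * pi * 0.05 * 0.3e-6, tolerance = 1e-6)
  r <- jkr_fit(fj)
  expect_equal(r$E, 6.26e6, tolerance = 1e-4)
  expect_equal(r$work_adhesion, 0.05, tolerance = 1e-4)
  # w fixed to zero agrees with the Hertz fit
  fh <- gen_force_curve(6.26e6, 0.3e-6, 0.33, 100e-9)
  expect_equal(jkr_fit(fh, work_adhesion = 0)$E, hertz_fit(fh),
               tolerance = 1e-9)
  # adhesion-free curve with free w falls back with a flag
  fb <- jkr_fit(fh)
  expect_true(fb$fallback)
  expect_equal(fb$E, hertz_fit(fh), tolerance = 1e-9)
})

test_that("Oliver-Pharr analysis recovers elastic unload curves", {
  fo <- gen_force_curve(5.97e6, 1e-6, 0.33, 20e-9, model = "jkr",
                        work_adhesion = 0)
  e <- oliver_pharr_fit(fo)
  expect_equal(e, 5.97e6, tolerance = 0.01)
  # window insensitivity on clean data
  e_full <- oliver_pharr_fit(fo, unload_upper = 1.0, unload_lower = 0.0)
  expect_equal(e, e_full, tolerance = 1e-3)
  # zero-force curve is rejected
  zero <- force_curve(seq(0, 1e-8, length.out = 20), rep(0, 20), "retract",
                      tip_radius = 1e-6)
  expect_error(oliver_pharr_fit(zero), "no positive force")
})

test_that("the three contact models agree on clean shallow curves", {
  fc <- gen_force_curve(6e6, 1e-6, 0.33, 20e-9)
  fr <- gen_force_curve(6e6, 1e-6, 0.33, 20e-9, model = "jkr",
                        work_adhesion = 0)
  eh <- hertz_fit(fc)
  ej <- jkr_fit(fr, work_adhesion = 0)$E
  eo <- oliver_pharr_fit(fr)
  expect_lt(abs(ej - eh) / eh, 0.02)
  expect_lt(abs(eo - eh) / eh, 0.02)
})

test_that("indentation ratio flags possible substrate see-through", {
  expect_equal(indentation_ratio(1e-9, 10e-9), 0.1)
  expect_warning(r <- indentation_ratio(4e-9, 10e-9), "substrate")
  expect_equal(r, 0.4)
  expect_equal(indentation_ratio(0, 10e-9), 0)
  expect_error(indentation_ratio(1e-9, 0), "feature_height")
})

test_that("force curves round-trip through the CSV format", {
  fc <- gen_force_curve(5e6, 0.5e-6, 0.33, 50e-9, noise_sd = 1e-9, seed = 4)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_force_curve_csv(fc, path)
  back <- read_force_curve_csv(path)
  expect_equal(back$force, fc$force, tolerance = 1e-10)
  expect_equal(back$tip_radius, 0.5e-6)
  expect_equal(back$segment, fc$segment)
})
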