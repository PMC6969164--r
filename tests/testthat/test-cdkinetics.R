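test_that("two-state decomposition inverts exact mixtures", {
  g <- cd_grid()
  s0 <- gen_basis_cd("unordered", g)
  s1 <- gen_basis_cd("beta_sheet", g)
  expect_equal(decompose_two_state(s0, s0, s1), 0)
  mix <- spectrum(g, 0.5 * s0$values + 0.5 * s1$values, "cd")
  expect_equal(decompose_two_state(mix, s0, s1), 0.5, tolerance = 1e-12)
  # scale invariance: common positive factor leaves the fraction unchanged
  sc <- function(s, a) spectrum(s$grid, a * s$values, s$kind)
  expect_equal(decompose_two_state(sc(mix, 7), sc(s0, 7), sc(s1, 7)),
               decompose_two_state(mix, s0, s1), tolerance = 1e-12)
  expect_error(decompose_two_state(mix, s0, sc(s0, 2)), "collinear")
  s0short <- spectrum(g[-1], s0$values[-1], "cd")
  expect_error(decompose_two_state(s0short, s0short, s1), "identical grid")
})

test_that("noisy decomposition agrees with a brute-force grid oracle", {
  g <- cd_grid()
  s0 <- gen_basis_cd("unordered", g)
  s1 <- gen_basis_cd("beta_sheet", g)
  rng <- diff(range(c(s0$values, s1$values)))
  set.seed(404)
  for (f_true in c(0.1, 0.3, 0.8)) {
    v <- (1 - f_true) * s0$values + f_true * s1$values +
      rnorm(length(g), 0, 0.01 * rng)
    s <- spectrum(g, v, "cd")
    # oracle: exhaustive search over f in {0, 0.001, ..., 1}
    fgrid <- seq(0, 1, by = 0.001)
    rss <- vapply(fgrid, function(f)
      sum((v - ((1 - f) * s0$values + f * s1$values))^2), numeric(1))
    f_oracle <- fgrid[which.min(rss)]
    expect_lt(abs(decompose_two_state(s, s0, s1) - f_oracle), 1.0001e-3)
  }
})

test_that("fraction_trace inverts a noiseless series and sorts by time", {
  p <- kinetic_params("logistic", k = 0.8, t_half = 6)
  times <- c(0, 2, 4, 6, 8, 12, 30)
  specs <- gen_cd_timeseries(p, times, noise_sd = 0)
  s0 <- gen_basis_cd("unordered", cd_grid())
  s1 <- gen_basis_cd("beta_sheet", cd_grid())
  tr <- fraction_trace(times, specs, s0, s1)
  expect_equal(tr$fractions, kinetic_curve(p, times), tolerance = 1e-9)
  # shuffled input comes back time-sorted with the same fractions
  o <- c(3, 1, 7, 5, 2, 6, 4)
  tr2 <- fraction_trace(times[o], specs[o], s0, s1)
  expect_equal(tr2$times, times)
  expect_equal(tr2$fractions, tr$fractions)
  # constant series pinned at the initial basis is all zero
  flat <- rep(list(s0), 5)
  expect_equal(fraction_trace(c(0, 1, 2, 3, 4), flat, s0, s1)$fractions,
               rep(0, 5))
  expect_error(fraction_trace(c(0, 1, 2), specs[1:3], s0, s1), "at least 4")
})

test_that("lag time follows t_lag = t_half - 1/(2k)", {
  expect_equal(lag_time(1, 10), 9.5)
  expect_equal(lag_time(0.05, 10), 0)
  expect_equal(lag_time(1e9, 10), 10, tolerance = 1e-9)
  expect_error(lag_time(0, 10), "k must be")
})

test_that("logistic fit is exact on noiseless data and flags bad spans", {
  tr <- gen_kinetic_trace(kinetic_params("logistic", k = 1, t_half = 10),
                          seq(0, 25, length.out = 50))
  f <- fit_logistic(tr)
  expect_equal(f$k, 1, tolerance = 1e-8)
  expect_equal(f$t_half, 10, tolerance = 1e-8)
  expect_equal(f$t_lag, 9.5, tolerance = 1e-8)
  expect_true(f$converged)
  # Eq.2-style identity holds exactly as computed
  expect_identical(f$t_lag, f$t_half - 1 / (2 * f$k))
  # constant trace cannot converge (span check)
  expect_false(fit_logistic(kinetic_trace(1:10, rep(0.1, 10)))$converged)
  expect_error(fit_logistic(kinetic_trace(1:10, c(rep(0.2, 9), NA))),
               "non-finite")
})

test_that("noisy logistic fits recover the generating parameters", {
  tr <- gen_kinetic_trace(kinetic_params("logistic", k = 0.5, t_half = 20),
                          seq(0, 45, length.out = 50),
                          noise_sd = 0.02, seed = 77)
  f <- fit_logistic(tr)
  expect_equal(f$k, 0.5, tolerance = 0.10)
  expect_equal(f$t_half, 20, tolerance = 0.05)
})

test_that("lag time decreases with growth rate at fixed midpoint", {
  lags <- vapply(c(0.3, 0.6, 1.2, 2.4), function(k) {
    tr <- gen_kinetic_trace(kinetic_params("logistic", k = k, t_half = 15),
                            seq(0, 40, length.out = 60))
    fit_logistic(tr)$t_lag
  }, numeric(1))
  expect_true(all(diff(lags) > 0))  # larger k -> t_lag closer to t_half
})

test_that("Avrami selection matches a brute-force (K, n) grid oracle", {
  oracle_n <- function(tr) {
    Kg <- 10^seq(-3, 1, length.out = 400)
    best <- vapply(1:4, function(n) {
      min(vapply(Kg, function(K)
        sum((tr$fractions - (1 - exp(-(K * tr$times)^n)))^2), numeric(1)))
    }, numeric(1))
    which.min(best)
  }
  for (n_true in c(1, 2, 3)) {
    tr <- gen_kinetic_trace(kinetic_params("avrami", K = 0.1, n = n_true),
                            seq(0, 40, length.out = 50))
    expect_equal(fit_avrami(tr)$n, n_true)
    expect_equal(fit_avrami(tr)$n, oracle_n(tr))
  }
  trn <- gen_kinetic_trace(kinetic_params("avrami", K = 0.1, n = 2),
                           seq(0, 30, length.out = 50),
                           noise_sd = 0.02, seed = 42)
  expect_equal(fit_avrami(trn)$n, 2L)
  expect_equal(fit_avrami(trn)$n, oracle_n(trn))
  expect_error(fit_avrami(trn, integer(0)), "empty")
})

test_that("seed-concentration scaling recovers exact linear laws", {
  conc <- c(0.5, 1, 2.5, 5, 7.5, 10)
  fits <- lapply(conc, function(cc) {
    k <- 0.1 + 0.03 * cc
    t_lag <- 5 - 2 * log10(cc)
    t_half <- t_lag + 1 / (2 * k)
    structure(list(k = k, t_half = t_half, t_lag = t_lag,
                   rss = 0, converged = TRUE), class = "logistic_fit")
  })
  sc <- fit_seed_scaling(conc, fits)
  expect_equal(sc$lag_scaling$slope, -2, tolerance = 1e-9)
  expect_equal(sc$lag_scaling$intercept, 5, tolerance = 1e-9)
  expect_equal(sc$lag_scaling$r_squared, 1, tolerance = 1e-9)
  expect_equal(sc$lag_scaling$x_transform, "log10")
  expect_equal(sc$rate_scaling$slope, 0.03, tolerance = 1e-9)
  expect_equal(sc$rate_scaling$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_seed_scaling(conc[1:2], fits[1:2]), "at least 3")
  expect_error(fit_seed_scaling(c(-1, 1, 2), fits[1:3]), "> 0")
})

test_that("kinetic traces round-trip through the CSV format", {
  tr <- gen_kinetic_trace(kinetic_params("logistic", k = 1, t_half = 5),
                          seq(0, 12, by = 0.5), noise_sd = 0.01, seed = 9,
                          label = "seeded-7.5pct", seed_conc = 7.5)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$times, tr$times)
  expect_equal(back$fractions, tr$fractions, tolerance = 1e-10)
  expect_equal(back$label, "seeded-7.5pct")
  expect_equal(back$seed_conc, 7.5)
})
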