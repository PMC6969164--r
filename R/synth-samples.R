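# Seeded scalar-sample generators (fibril widths, modulus maps) and the
# kinetic-trace generator.

#' Synthetic fraction-completion trace
#'
#' Evaluates the kinetic model at the requested times and adds Gaussian
#' noise. Values are deliberately not clamped to [0, 1]: the fitters operate
#' on raw fractions so that noise near the plateaus does not bias them.
#'
#' @inheritParams gen_cd_timeseries
#' @param label experiment identifier carried on the trace.
#' @param seed_conc optional seed concentration (wt%) carried on the trace.
#' @return A [kinetic_trace()].
#' @examples
#' tr <- gen_kinetic_trace(kinetic_params("avrami", K = 0.1, n = 2),
#'                         times = seq(0, 30, length.out = 50))
#' @export
gen_kinetic_trace <- function(params, times, noise_sd = 0, seed = NULL,
                              label = "", seed_conc = NULL) {
  if (length(times) == 0 || any(diff(times) < 0))
    stop_input("times must be non-empty and non-decreasing")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  y <- kinetic_curve(params, times)
  with_seed(seed, {
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    kinetic_trace(times, y, label = label, seed_conc = seed_conc)
  })
}

#' Seeded normal and log-normal samples
#'
#' `gen_normal_sample` draws i.i.d. values from N(mu, sigma^2), the model
#' used for fibril-width histograms. `gen_lognormal_sample` draws from the
#' log-normal distribution whose *arithmetic* mean and standard deviation
#' equal `mean` and `sd`, matching how AM-FM modulus histograms are reported
#' (mean +/- sd of the fitted log-normal).
#'
#' @param mu,sigma normal parameters; `sigma > 0`.
#' @param mean,sd arithmetic mean and sd of the log-normal; both > 0.
#' @param n sample size, >= 2.
#' @param seed optional RNG seed.
#' @return Numeric vector of length `n`.
#' @examples
#' w <- gen_normal_sample(34, 9, 160, seed = 1)
#' e <- gen_lognormal_sample(4.18, 0.71, 1000, seed = 1)
#' @export
gen_normal_sample <- function(mu, sigma, n, seed = NULL) {
  if (sigma <= 0) stop_input("sigma must be > 0")
  if (n < 2) stop_input("n must be >= 2")
  with_seed(seed, stats::rnorm(n, mu, sigma))
}

#' @rdname gen_normal_sample
#' @export
gen_lognormal_sample <- function(mean, sd, n, seed = NULL) {
  if (sd <= 0) stop_input("sd must be > 0")
  if (mean <= 0) stop_input("mean must be > 0")
  if (n < 2) stop_input("n must be >= 2")
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  with_seed(seed, stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2)))
}
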