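# Two-state CD decomposition and kinetic fitting.

#' Two-state spectral decomposition
#'
#' Fits an observed CD spectrum as a linear combination of the initial
#' (time-zero, unordered) and final (equilibrium, beta-sheet) spectra with a
#' single bounded mixing weight: the fraction completion f minimizing
#' ||S - ((1 - f) S0 + f Sinf)||^2 subject to f in [0, 1]. The closed-form
#' unconstrained minimizer is projected onto [0, 1].
#'
#' @param spectrum observed [spectrum()].
#' @param basis_initial initial-state basis spectrum (same grid).
#' @param basis_final final-state basis spectrum (same grid).
#' @return Fraction completion in [0, 1].
#' @examples
#' g <- 185:260
#' s0 <- gen_basis_cd("unordered", g); s1 <- gen_basis_cd("beta_sheet", g)
#' mix <- spectrum(g, 0.5 * s0$values + 0.5 * s1$values, "cd")
#' decompose_two_state(mix, s0, s1)  # 0.5
#' @export
decompose_two_state <- function(spectrum, basis_initial, basis_final) {
  stopifnot(is_spectrum(spectrum), is_spectrum(basis_initial),
            is_spectrum(basis_final))
  check_same_grid(spectrum, basis_initial, basis_final)
  v0 <- basis_initial$values
  v1 <- basis_final$values
  # collinearity guard: proportional bases make the two-state model degenerate
  n0 <- sqrt(sum(v0^2)); n1 <- sqrt(sum(v1^2))
  if (n0 == 0 || n1 == 0 ||
      1 - abs(sum(v0 * v1)) / (n0 * n1) < 1e-10)
    stop_input("degenerate basis: initial and final spectra are collinear")
  d <- v1 - v0
  f <- sum((spectrum$values - v0) * d) / sum(d * d)
  min(1, max(0, f))
}

#' Fraction-completion trace from a CD time series
#'
#' Applies [decompose_two_state()] to each spectrum of a time series. By
#' default the initial basis is the first (time-sorted) spectrum and the
#' final basis is the last, matching the convention that the equilibrium
#' spectrum is the one that no longer changes; explicit bases override this.
#'
#' @param times observation times (h), one per spectrum.
#' @param spectra list of [spectrum()] objects on a common grid.
#' @param basis_initial,basis_final optional explicit basis spectra.
#' @param label experiment identifier for the returned trace.
#' @return A [kinetic_trace()], time-sorted.
#' @export
fraction_trace <- function(times, spectra, basis_initial = NULL,
                           basis_final = NULL, label = "") {
  if (length(times) != length(spectra))
    stop_input("times and spectra must have equal length")
  if (length(times) < 4)
    stop_input("need at least 4 time points for a kinetic trace")
  o <- order(times)
  times <- times[o]; spectra <- spectra[o]
  if (is.null(basis_initial)) basis_initial <- spectra[[1]]
  if (is.null(basis_final)) basis_final <- spectra[[length(spectra)]]
  f <- vapply(spectra, decompose_two_state, numeric(1),
              basis_initial = basis_initial, basis_final = basis_final)
  kinetic_trace(times, f, label = label)
}

#' Lag time of a logistic kinetic curve
#'
#' The apparent nucleation delay `t_lag = t_half - 1/(2 k)`: the intercept
#' of the tangent at the midpoint with the baseline.
#'
#' @param k logistic growth rate (1/h), > 0.
#' @param t_half midpoint time (h).
#' @return Lag time (h).
#' @examples
#' lag_time(1, 10)     # 9.5
#' lag_time(0.05, 10)  # 0
#' @export
lag_time <- function(k, t_half) {
  if (!is.finite(k) || k <= 0) stop_input("k must be > 0")
  t_half - 1 / (2 * k)
}

#' Fit the logistic assembly model
#'
#' Least-squares fit of `y = 1 / (1 + exp(-k (t - t_half)))` to a
#' fraction-completion trace. Deterministic initialization: `t_half` starts
#' at the first linear-interpolated crossing of y = 0.5 and `k` at
#' `4 / (t90 - t10)`. A trace whose fractions do not span at least
#' [0.2, 0.8] is flagged non-converged (the plateaus are not identifiable).
#'
#' @param trace a [kinetic_trace()] with >= 4 points.
#' @return An object of class `logistic_fit`: list with `k`, `t_half`,
#'   `t_lag` (= `t_half - 1/(2k)` exactly), `rss`, `converged`.
#' @export
fit_logistic <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$times; y <- trace$fractions
  if (length(t) < 4) stop_input("need at least 4 points")
  if (any(!is.finite(y))) stop_input("non-finite fractions")
  span_ok <- min(y) <= 0.2 && max(y) >= 0.8

  cross <- function(level) {
    i <- which(y >= level)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(t[1])
    t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  t50 <- cross(0.5); t10 <- cross(0.1); t90 <- cross(0.9)
  if (!is.finite(t50)) t50 <- stats::median(t)
  k0 <- if (is.finite(t10) && is.finite(t90) && t90 > t10) 4 / (t90 - t10) else 1

  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(k = k0, th = t50),
                       fn = function(p) y - 1 / (1 + exp(-p[1] * (t - p[2]))),
                       lower = c(1e-8, -Inf),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)

  if (is.null(fit) || !fit$info %in% 1:4) {
    out <- list(k = NA_real_, t_half = NA_real_, t_lag = NA_real_,
                rss = NA_real_, converged = FALSE)
  } else {
    cf <- fit$par
    out <- list(k = unname(cf["k"]), t_half = unname(cf["th"]),
                t_lag = lag_time(unname(cf["k"]), unname(cf["th"])),
                rss = sum(fit$fvec^2),
                converged = span_ok)
  }
  structure(out, class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> k = %.4g 1/h, t_half = %.4g h, t_lag = %.4g h (%s)\n",
    x$k, x$t_half, x$t_lag,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit the Avrami (JMAK) model with dimensionality selection
#'
#' For each candidate integer exponent n, fits the rate constant K of
#' `y = 1 - exp(-(K t)^n)` by 1-D least squares over log K, then selects the
#' n with the smallest residual sum of squares. The exponent is the growth
#' dimensionality of the transformation.
#'
#' @param trace a [kinetic_trace()] with >= 4 points.
#' @param n_candidates integer candidate exponents (default 1:4).
#' @return An object of class `avrami_fit`: list with `K`, `n`, `rss`,
#'   `rss_by_n` (named numeric), `K_by_n`.
#' @export
fit_avrami <- function(trace, n_candidates = 1:4) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (length(n_candidates) == 0) stop_input("empty candidate set")
  if (any(n_candidates < 1 | n_candidates != round(n_candidates)))
    stop_input("candidates must be integers >= 1")
  t <- trace$times; y <- trace$fractions
  if (length(t) < 4) stop_input("need at least 4 points")
  if (any(!is.finite(y))) stop_input("non-finite fractions")

  rss_of <- function(logK, n) {
    sum((y - (1 - exp(-(exp(logK) * t)^n)))^2)
  }
  Ks <- rss <- stats::setNames(numeric(length(n_candidates)),
                               as.character(n_candidates))
  for (i in seq_along(n_candidates)) {
    n <- n_candidates[i]
    opt <- stats::optimize(rss_of, interval = log(c(1e-6, 1e4)), n = n,
                           tol = .Machine$double.eps^0.5)
    # polish with a second, narrower pass for near-machine recovery
    opt <- stats::optimize(rss_of, n = n,
                           interval = opt$minimum + c(-0.05, 0.05),
                           tol = .Machine$double.eps^0.6)
    Ks[i] <- exp(opt$minimum)
    rss[i] <- opt$objective
  }
  best <- which.min(rss)
  structure(list(K = unname(Ks[best]),
                 n = as.integer(n_candidates[best]),
                 rss = unname(rss[best]),
                 rss_by_n = rss, K_by_n = Ks),
            class = "avrami_fit")
}

#' @export
print.avrami_fit <- function(x, ...) {
  cat(sprintf("<avrami_fit> n = %d (growth dimensionality), K = %.4g 1/h\n",
              x$n, x$K))
  invisible(x)
}

#' Seed-concentration scaling of lag time and growth rate
#'
#' Ordinary least squares of the fitted lag times on log10(seed
#' concentration) and of the fitted growth rates on seed concentration,
#' the two scaling laws characterizing templated assembly: lag time falls
#' linearly with the logarithm of seed concentration while growth rate
#' rises linearly with it.
#'
#' @param seed_conc seed concentrations (wt%), all > 0, >= 3 values.
#' @param fits list of `logistic_fit` objects, one per concentration.
#' @return List with `lag_scaling` and `rate_scaling`, each of class
#'   `scaling_fit` (slope, intercept, r_squared, x_transform).
#' @export
fit_seed_scaling <- function(seed_conc, fits) {
  if (length(seed_conc) != length(fits))
    stop_input("seed_conc and fits must have equal length")
  if (length(seed_conc) < 3)
    stop_input("need at least 3 concentrations")
  if (any(seed_conc <= 0))
    stop_input("seed concentrations must be > 0 (log transform)")
  t_lag <- vapply(fits, function(f) f$t_lag, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))

  line <- function(x, y, transform) {
    m <- stats::lm(y ~ x)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(m)^2) / tss
    structure(list(slope = unname(stats::coef(m)[2]),
                   intercept = unname(stats::coef(m)[1]),
                   r_squared = r2,
                   x_transform = transform),
              class = "scaling_fit")
  }
  list(lag_scaling = line(log10(seed_conc), t_lag, "log10"),
       rate_scaling = line(seed_conc, k, "identity"))
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> y = %.4g + %.4g * %s(x), r^2 = %.4f\n",
              x$intercept, x$slope,
              if (x$x_transform == "log10") "log10" else "", x$r_squared))
  invisible(x)
}
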