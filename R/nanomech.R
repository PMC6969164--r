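# Nanomechanics: modulus-histogram fitting and contact-mechanics
# force-curve inversion (Hertz, JKR, Oliver-Pharr).

#' Log-normal fit of a modulus histogram
#'
#' Fits a log-normal distribution to per-pixel Young's moduli (AM-FM or
#' force-map histograms) on the log scale and reports both the log-space
#' parameters and the arithmetic mean and standard deviation of the fitted
#' distribution, the convention used for AM-FM modulus summaries.
#'
#' @param values moduli (Pa), all > 0, n >= 30.
#' @param source optional provenance tag (`"amfm"`, `"forcemap"`, ...).
#' @return An object of class `lognormal_fit`: list with `mean`, `sd`
#'   (arithmetic moments of the fitted distribution), `mu_log`,
#'   `sigma_log`, `n`, `source`.
#' @examples
#' fit_lognormal(gen_lognormal_sample(4.18e9, 0.71e9, 1000, seed = 1))
#' @export
fit_lognormal <- function(values, source = NULL) {
  values <- as.numeric(values)
  if (length(values) < 30) stop_input("need at least 30 values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop_input("all values must be finite and > 0")
  lx <- log(values)
  mu <- mean(lx)
  s <- stats::sd(lx)
  m <- exp(mu + s^2 / 2)
  structure(list(mean = m, sd = m * sqrt(exp(s^2) - 1),
                 mu_log = mu, sigma_log = s,
                 n = length(values), source = source),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> %.4g +/- %.4g Pa (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Gaussian fit of a modulus sample
#'
#' Normal fit of per-curve Young's moduli (e.g. the 216 Hertz-fitted gel
#' indentation curves); same estimator as [fit_normal()] with the
#' histogram-fitting minimum of 30 values.
#'
#' @param values moduli (Pa), n >= 30.
#' @param source optional provenance tag.
#' @return A `normal_fit` object.
#' @export
fit_gaussian_moduli <- function(values, source = NULL) {
  fit_normal(values, stage = source, min_n = 30L)
}

# Contact region of a curve: prefer the requested segment, re-zero the
# contact point when pre-contact (negative-indentation) data are present.
contact_region <- function(curve, segment = "approach") {
  sel <- curve$segment == segment
  if (!any(sel)) sel <- rep(TRUE, length(curve$force))
  d <- curve$indentation[sel]; f <- curve$force[sel]
  if (any(d < 0)) {
    pre <- f[d < 0]
    thr <- 3 * stats::sd(pre)
    if (!is.finite(thr) || thr == 0) thr <- 0
    idx <- which(d >= 0 & f > thr)[1]
    if (is.na(idx)) stop_input("no contact point found")
    d0 <- d[idx]
    keep <- d >= d0
    d <- d[keep] - d0; f <- f[keep]
  }
  list(delta = d, force = f)
}

#' Hertz contact fit of a force curve
#'
#' Least-squares fit of the Hertz sphere-on-halfspace relation
#' `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)` over the contact region
#' (rigid-indenter reduced modulus). Linear in `delta^(3/2)`, so the fit is
#' a closed-form regression through the origin.
#'
#' @param curve a [force_curve()] with an approach segment; indentation
#'   already zeroed at contact, or containing pre-contact data from which
#'   the contact point is detected (first force above 3x the pre-contact
#'   noise sd).
#' @return Young's modulus E (Pa).
#' @export
hertz_fit <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  cr <- contact_region(curve, "approach")
  keep <- cr$delta > 0
  if (sum(keep) < 10) stop_input("need at least 10 contact points")
  d <- cr$delta[keep]; f <- cr$force[keep]
  xx <- d^1.5
  slope <- sum(f * xx) / sum(xx^2)
  0.75 * slope * (1 - curve$poisson^2) / sqrt(curve$tip_radius)
}

#' JKR contact fit of a force curve
#'
#' Least-squares fit of the JKR indentation-force relation (see
#' [gen_force_curve()] for the closed forms) to an adhesive retract curve,
#' estimating Young's modulus and the work of adhesion jointly. Residuals
#' are taken in indentation as a function of force. With
#' `work_adhesion = 0` the relation reduces to Hertz and the Hertz fit is
#' returned. If adhesion is requested free but the curve shows no pull-off
#' (no negative force), the fit falls back to Hertz with a flag.
#'
#' @param curve a [force_curve()] with a retract segment.
#' @param work_adhesion fix w (J/m^2) instead of fitting it; `NULL` fits w.
#' @return List with `E` (Pa), `work_adhesion` (J/m^2), `rss`, `fallback`
#'   (TRUE when a pull-off-free curve was fit as Hertz).
#' @export
jkr_fit <- function(curve, work_adhesion = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  R <- curve$tip_radius; nu <- curve$poisson
  if (!is.null(work_adhesion) && work_adhesion == 0)
    return(list(E = hertz_fit(curve), work_adhesion = 0, rss = 0,
                fallback = FALSE))
  sel <- curve$segment == "retract"
  if (!any(sel)) sel <- rep(TRUE, length(curve$force))
  d <- curve$indentation[sel]; f <- curve$force[sel]
  if (min(f) >= 0 && is.null(work_adhesion)) {
    return(list(E = hertz_fit(curve), work_adhesion = 0, rss = NA_real_,
                fallback = TRUE))
  }
  dscale <- max(abs(d))
  pred_delta <- function(E, w) {
    Kbar <- (4 / 3) * E / (1 - nu^2)
    a <- jkr_a_from_F(f, w, R, Kbar)
    jkr_delta_from_a(a, w, R, Kbar)
  }
  obj <- function(p) {
    E <- exp(p[1]); w <- exp(p[2])
    if (min(f) < -1.5 * pi * w * R) return(1e6)  # infeasible pull-off
    dp <- pred_delta(E, w)
    if (any(!is.finite(dp))) return(1e6)
    sum(((dp - d) / dscale)^2)
  }
  # initialization: Hertz on the upper half for E, pull-off force for w
  fmax <- max(f); imax <- which.max(f)
  E0 <- 0.75 * fmax * (1 - nu^2) / (sqrt(R) * max(d[imax], dscale)^1.5)
  w0 <- if (!is.null(work_adhesion)) work_adhesion else
    max(-2 * min(f) / (3 * pi * R), 1e-9)
  if (!is.null(work_adhesion)) {
    opt <- stats::optimize(function(lE) obj(c(lE, log(w0))),
                           interval = log(E0) + c(-4, 4),
                           tol = .Machine$double.eps^0.5)
    return(list(E = exp(opt$minimum), work_adhesion = work_adhesion,
                rss = opt$objective * dscale^2, fallback = FALSE))
  }
  opt <- stats::optim(c(log(E0), log(w0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  # polish around the optimum
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  list(E = exp(opt$par[1]), work_adhesion = exp(opt$par[2]),
       rss = opt$value * dscale^2, fallback = FALSE)
}

#' Oliver-Pharr analysis of an unloading curve
#'
#' Fits the power law `F = alpha (delta - delta_f)^m` to the unload branch
#' between `unload_lower` and `unload_upper` fractions of the peak force
#' (95% and 20% by default), evaluates the contact stiffness
#' `S = dF/ddelta` at peak, the contact depth
#' `h_c = delta_max - 0.75 F_max / S`, the spherical contact area
#' `A = pi (2 R h_c - h_c^2)`, the reduced modulus
#' `E_r = S sqrt(pi) / (2 sqrt(A))`, and returns the Young's modulus
#' `E = (1 - nu^2) E_r` (rigid indenter).
#'
#' @param curve a [force_curve()] whose retract/unload branch is monotone
#'   in force between the limits.
#' @param unload_upper,unload_lower window limits as fractions of peak
#'   force.
#' @return Young's modulus E (Pa).
#' @export
oliver_pharr_fit <- function(curve, unload_upper = 0.95,
                             unload_lower = 0.20) {
  stopifnot(inherits(curve, "force_curve"))
  sel <- curve$segment == "retract"
  if (!any(sel)) sel <- rep(TRUE, length(curve$force))
  d <- curve$indentation[sel]; f <- curve$force[sel]
  fmax <- max(f)
  if (fmax <= 0) stop_input("no positive force on the unload branch")
  dmax <- d[which.max(f)]
  win <- f >= unload_lower * fmax & f <= unload_upper * fmax
  if (sum(win) < 5) stop_input("too few points in the unload window")
  dw <- d[win]; fw <- f[win]
  o <- order(dw)
  if (any(diff(fw[o]) < 0))
    stop_input("unload window is not monotone in force")

  # dimensionless fit for numerical conditioning
  dh <- dw / dmax; fh <- fw / fmax
  resid_fn <- function(p) fh - p[1] * (dh - p[2])^p[3]
  fit <- minpack.lm::nls.lm(
    par = c(A = 1, df = min(dh) - 0.5, m = 1.5), fn = resid_fn,
    lower = c(1e-8, -10, 1.01), upper = c(Inf, min(dh) - 1e-9, 5),
    control = minpack.lm::nls.lm.control(maxiter = 500,
                                         ftol = 1e-15, ptol = 1e-15))
  cf <- fit$par
  S <- (fmax / dmax) * cf["A"] * cf["m"] * (1 - cf["df"])^(cf["m"] - 1)
  S <- unname(S)
  hc <- dmax - 0.75 * fmax / S
  R <- curve$tip_radius
  if (hc <= 0 || hc >= 2 * R)
    stop_input("contact depth outside the spherical area function range")
  A <- pi * (2 * R * hc - hc^2)
  Er <- S * sqrt(pi) / (2 * sqrt(A))
  (1 - curve$poisson^2) * Er
}

#' Indentation-depth to feature-height ratio
#'
#' Diagnostic for substrate "see-through" in AM-FM scans of nanoscale
#' features: ratios above 0.3 indicate that the measured modulus may be
#' contaminated by the substrate, and a warning is emitted.
#'
#' @param depth indentation depth (m), >= 0.
#' @param feature_height feature height (m), > 0.
#' @return The ratio depth/height.
#' @export
indentation_ratio <- function(depth, feature_height) {
  if (feature_height <= 0) stop_input("feature_height must be > 0")
  if (depth < 0) stop_input("depth must be >= 0")
  r <- depth / feature_height
  if (r > 0.3)
    warning("indentation ratio above 0.3: possible substrate effect",
            call. = FALSE)
  r
}
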