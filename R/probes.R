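# Fluorescent-probe analyses: ANS emission peak, pyrene I1/I3 ratio, and
# the micellization breakpoint in a concentration series.

#' Emission peak wavelength
#'
#' Wavelength of the global emission maximum after 5-point smoothing, with
#' parabolic sub-grid refinement through the peak sample and its two
#' neighbours. Used to read the ANS blue shift (520 nm free in solution,
#' 470 nm bound to hydrophobic silk surfaces).
#'
#' @param spec a fluorescence [spectrum()] with >= 8 points.
#' @return Peak wavelength (nm).
#' @export
emission_peak <- function(spec) {
  stopifnot(is_spectrum(spec))
  v <- moving_average(spec$values, 5L)
  if (diff(range(v)) == 0)
    stop_input("no emission peak: spectrum is constant")
  i <- which.max(v)
  g <- spec$grid
  if (i == 1L || i == length(v)) return(g[i])
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (abs(denom) < .Machine$double.eps * max(abs(v))) return(g[i])
  # vertex of the parabola through the three points (uniform local spacing)
  h <- (g[i + 1] - g[i - 1]) / 2
  g[i] + 0.5 * h * (v[i - 1] - v[i + 1]) / denom
}

#' Pyrene I1/I3 vibronic band ratio
#'
#' Mean intensity over the closed window 371-376 nm (first vibronic band,
#' I1) divided by the mean over 398-403 nm (third band, I3). The ratio
#' falls as pyrene partitions into hydrophobic microenvironments, so its
#' concentration dependence reports micelle formation.
#'
#' @param spec a fluorescence [spectrum()] whose grid covers both windows.
#' @return I1/I3 ratio.
#' @export
pyrene_ratio <- function(spec) {
  stopifnot(is_spectrum(spec))
  g <- spec$grid
  in1 <- g >= 371 & g <= 376
  in3 <- g >= 398 & g <= 403
  if (!any(in1) || !any(in3))
    stop_input("grid must cover the 371-376 and 398-403 nm windows")
  i3 <- mean(spec$values[in3])
  if (i3 <= 0) stop_input("I3 window mean is not positive")
  mean(spec$values[in1]) / i3
}

#' Concentration series of I1/I3 ratios
#'
#' @param concentrations strictly increasing concentrations (mg/ml), > 0.
#' @param ratios I1/I3 values, same length.
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(concentrations, ratios) {
  concentrations <- as.numeric(concentrations)
  ratios <- as.numeric(ratios)
  if (length(concentrations) != length(ratios))
    stop_input("concentrations and ratios must have equal length")
  if (any(concentrations <= 0))
    stop_input("concentrations must be > 0")
  if (any(diff(concentrations) <= 0))
    stop_input("concentrations must be strictly increasing")
  structure(list(concentrations = concentrations, ratios = ratios),
            class = "concentration_series")
}

#' Micellization breakpoint by segmented regression
#'
#' Continuous two-segment piecewise-linear fit of I1/I3 against
#' log10(concentration). The breakpoint is chosen by exhaustive search over
#' the midpoints between consecutive observed log-concentrations,
#' minimizing the total residual sum of squares; continuity at the break is
#' enforced by the parameterization `y = a + b x + c (x - xb)_+`. The
#' back-transformed breakpoint (mg/ml) estimates the critical micelle
#' concentration.
#'
#' @param series a [concentration_series()] with >= 6 points spanning at
#'   least 2 decades.
#' @return An object of class `inflection_fit`: list with `breakpoint`
#'   (mg/ml), `slope_left`, `slope_right`, `rss`.
#' @export
find_inflection <- function(series) {
  stopifnot(inherits(series, "concentration_series"))
  cc <- series$concentrations; y <- series$ratios
  if (length(cc) < 6)
    stop_input("need at least 6 concentrations")
  if (max(cc) / min(cc) < 100 * (1 - 1e-9))
    stop_input("concentrations must span at least 2 decades")
  x <- log10(cc)
  cands <- (x[-1] + x[-length(x)]) / 2
  best <- NULL
  for (xb in cands) {
    X <- cbind(1, x, pmax(x - xb, 0))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      b <- fit$coefficients
      best <- list(xb = xb, rss = rss,
                   slope_left = unname(b[2]),
                   slope_right = unname(b[2] + b[3]))
    }
  }
  structure(list(breakpoint = 10^best$xb,
                 slope_left = best$slope_left,
                 slope_right = best$slope_right,
                 rss = best$rss),
            class = "inflection_fit")
}

#' @export
print.inflection_fit <- function(x, ...) {
  cat(sprintf(
    "<inflection_fit> breakpoint %.3g mg/ml, slopes %.3g -> %.3g\n",
    x$breakpoint, x$slope_left, x$slope_right))
  invisible(x)
}
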