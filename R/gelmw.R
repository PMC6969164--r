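# SDS-PAGE densitometry: ladder calibration, lane-to-distribution
# conversion, and molecular-weight statistics.

#' Ladder calibration: pixel position to molecular weight
#'
#' Detects the ladder band peaks (local maxima of the lightly smoothed
#' profile above 20% of the maximum) and builds a monotone piecewise-linear
#' map between pixel position and log10(MW), with linear extrapolation
#' beyond the outermost bands. Band count must equal the number of supplied
#' standards.
#'
#' @param ladder a [lane_profile()] of the standards lane.
#' @param ladder_mws standard molecular weights (kDa), strictly decreasing
#'   along the migration direction; >= 3.
#' @return An object of class `ladder_calibration`: list with
#'   `band_positions`, `band_mws`, and the map functions `mw_at(position)`
#'   and `position_at(mw)`.
#' @export
calibrate_ladder <- function(ladder, ladder_mws) {
  stopifnot(inherits(ladder, "lane_profile"))
  ladder_mws <- as.numeric(ladder_mws)
  if (length(ladder_mws) < 3)
    stop_input("calibration needs at least 3 ladder bands")
  if (any(diff(ladder_mws) >= 0))
    stop_input("ladder_mws must be strictly decreasing along migration")
  v <- moving_average(ladder$intensities, 5L)
  idx <- local_maxima(v)
  idx <- idx[v[idx] >= 0.2 * max(v)]
  if (length(idx) != length(ladder_mws))
    stop_input(sprintf(
      "calibration error: found %d band peaks for %d standards",
      length(idx), length(ladder_mws)))
  pos <- ladder$positions[idx]
  lM <- log10(ladder_mws)

  interp_lin <- function(xk, yk) {
    # piecewise-linear through the knots, linear extrapolation at the ends
    function(x) {
      y <- stats::approx(xk, yk, xout = x, rule = 2)$y
      lo <- x < xk[1]
      hi <- x > xk[length(xk)]
      if (any(lo)) {
        s <- (yk[2] - yk[1]) / (xk[2] - xk[1])
        y[lo] <- yk[1] + s * (x[lo] - xk[1])
      }
      if (any(hi)) {
        nk <- length(xk)
        s <- (yk[nk] - yk[nk - 1]) / (xk[nk] - xk[nk - 1])
        y[hi] <- yk[nk] + s * (x[hi] - xk[nk])
      }
      y
    }
  }
  log_mw_at <- interp_lin(pos, lM)
  pos_at_logmw <- interp_lin(rev(lM), rev(pos))
  structure(list(band_positions = pos, band_mws = ladder_mws,
                 mw_at = function(position) 10^log_mw_at(position),
                 position_at = function(mw) pos_at_logmw(log10(mw))),
            class = "ladder_calibration")
}

#' Molecular-weight distribution container
#'
#' Weight-fraction density over molecular weight, normalized to integrate
#' to 1, with summary statistics attached by [mw_stats()].
#'
#' @param mw_grid increasing molecular weights (kDa).
#' @param density non-negative weight-fraction density, normalized
#'   internally to unit integral.
#' @return An object of class `mw_distribution` with elements `mw_grid`,
#'   `density`, `mw_range`, `Mn`, `Mw`, `PDI`.
#' @export
mw_distribution <- function(mw_grid, density) {
  mw_grid <- as.numeric(mw_grid); density <- as.numeric(density)
  if (length(mw_grid) != length(density))
    stop_input("mw_grid and density must have equal length")
  if (any(diff(mw_grid) <= 0))
    stop_input("mw_grid must be strictly increasing")
  if (any(density < 0)) stop_input("density must be non-negative")
  tot <- pracma::trapz(mw_grid, density)
  if (tot <= 0) stop_input("density integrates to zero")
  density <- density / tot
  out <- structure(list(mw_grid = mw_grid, density = density),
                   class = "mw_distribution")
  st <- mw_stats(out)
  out$mw_range <- st$mw_range; out$Mn <- st$Mn; out$Mw <- st$Mw
  out$PDI <- st$PDI
  out
}

#' @export
print.mw_distribution <- function(x, ...) {
  cat(sprintf(
    "<mw_distribution> range %.3g-%.3g kDa, Mn = %.4g, Mw = %.4g, PDI = %.3f\n",
    x$mw_range[1], x$mw_range[2], x$Mn, x$Mw, x$PDI))
  invisible(x)
}

#' Lane profile to molecular-weight distribution
#'
#' Min-max normalizes the lane intensities to [0, 1], removes background
#' (pixels below `background_threshold` of the maximum are zeroed; band
#' intensities are assumed already inverted so that bands are bright), maps
#' pixel positions to molecular weight through the ladder calibration, and
#' converts intensity per pixel to weight-fraction density per kDa with the
#' Jacobian |dp/dM| of the calibration map.
#'
#' @param lane a [lane_profile()].
#' @param cal a [calibrate_ladder()] result.
#' @param background_threshold background cutoff as a fraction of the
#'   normalized maximum (default 0.05).
#' @return An [mw_distribution()].
#' @export
lane_to_distribution <- function(lane, cal, background_threshold = 0.05) {
  stopifnot(inherits(lane, "lane_profile"),
            inherits(cal, "ladder_calibration"))
  v <- lane$intensities
  rng <- range(v)
  if (diff(rng) == 0) stop_input("empty lane: constant intensity")
  v <- (v - rng[1]) / diff(rng)
  v[v < background_threshold] <- 0
  if (all(v == 0)) stop_input("empty lane: all pixels below threshold")
  M <- cal$mw_at(lane$positions)
  # dM/dp along the lane (MW decreases with migration distance)
  dMdp <- pracma::gradient(M, lane$positions)
  w <- v / abs(dMdp)
  o <- order(M)
  mw_distribution(M[o], w[o])
}

#' Molecular-weight statistics of a distribution
#'
#' Treating the density as weight fraction w(M): the weight-average
#' `Mw = integral M w(M) dM`, the number-average
#' `Mn = 1 / integral (w(M)/M) dM`, the polydispersity index `PDI = Mw/Mn`
#' (>= 1, with equality only for a monodisperse sample), and the MW range
#' where the density exceeds 1e-4 of its maximum.
#'
#' @param dist an [mw_distribution()], or any list with `mw_grid` and
#'   `density`.
#' @return List with `mw_range` (kDa), `Mn`, `Mw`, `PDI`.
#' @export
mw_stats <- function(dist) {
  M <- dist$mw_grid; w <- dist$density
  tot <- pracma::trapz(M, w)
  w <- w / tot
  Mw <- pracma::trapz(M, M * w)
  Mn <- 1 / pracma::trapz(M, w / M)
  nz <- M[w > 1e-4 * max(w)]
  list(mw_range = range(nz), Mn = Mn, Mw = Mw, PDI = Mw / Mn)
}
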