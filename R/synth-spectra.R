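# Synthetic spectroscopic data generators. Every generator is a pure
# function of (parameters, seed): identical inputs give identical output.

#' Basis CD spectra for the two-state model
#'
#' Returns the reference circular-dichroism spectrum of one conformational
#' state of silk fibroin as a minimal sum of Gaussian bands reproducing the
#' characteristic band positions: the beta-sheet state has a positive band
#' centered at 196 nm and a negative band at 218 nm; the unordered
#' (random-coil) state has a single negative band at 198 nm.
#'
#' @param conformation `"unordered"` or `"beta_sheet"`.
#' @param grid wavelengths (nm) covering at least 185-260 nm.
#' @return A [spectrum()] of kind `"cd"` (values in mdeg).
#' @examples
#' b <- gen_basis_cd("beta_sheet", 185:260)
#' b$grid[which.max(b$values)]  # 196
#' @export
gen_basis_cd <- function(conformation = c("unordered", "beta_sheet"),
                         grid = seq(185, 260, by = 1)) {
  conformation <- match.arg(conformation)
  grid <- as.numeric(grid)
  if (min(grid) > 185 || max(grid) < 260)
    stop_input("CD grid must cover 185-260 nm")
  v <- if (conformation == "beta_sheet") {
    gauss_height(grid, 196, 12,  8) + gauss_height(grid, 218, 16, -6)
  } else {
    gauss_height(grid, 198, 14, -12)
  }
  spectrum(grid, v, kind = "cd")
}

#' Time series of CD spectra along an assembly trajectory
#'
#' Each spectrum at time t is the exact linear two-state mixture
#' `(1 - y(t)) * unordered + y(t) * beta_sheet` evaluated from the kinetic
#' model, plus additive i.i.d. Gaussian noise.
#'
#' @param params a [kinetic_params()].
#' @param times non-empty, non-decreasing observation times (h).
#' @param noise_sd Gaussian noise standard deviation (mdeg), >= 0.
#' @param seed optional RNG seed for the noise draws.
#' @param grid wavelength grid (nm), passed to [gen_basis_cd()].
#' @return A list of [spectrum()] objects, one per time.
#' @export
gen_cd_timeseries <- function(params, times, noise_sd = 0, seed = NULL,
                              grid = seq(185, 260, by = 1)) {
  if (length(times) == 0 || any(diff(times) < 0))
    stop_input("times must be non-empty and non-decreasing")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  s0 <- gen_basis_cd("unordered", grid)
  s1 <- gen_basis_cd("beta_sheet", grid)
  y <- kinetic_curve(params, times)
  with_seed(seed, {
    lapply(seq_along(times), function(i) {
      v <- (1 - y[i]) * s0$values + y[i] * s1$values
      if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
      spectrum(grid, v, kind = "cd")
    })
  })
}

#' Synthetic FTIR Amide I spectrum from a band table
#'
#' Builds an absorbance spectrum on the Amide I window (1595-1705 cm^-1) as a
#' sum of Gaussian component bands with prescribed area fractions, the
#' forward model inverted by [fit_amide1()].
#'
#' @param band_table data frame with columns `center` (cm^-1), `fwhm`
#'   (cm^-1), `area` (fractions summing to 1).
#' @param grid wavenumber grid (cm^-1).
#' @param noise_sd additive Gaussian noise sd (absorbance), >= 0.
#' @param seed optional RNG seed.
#' @param total_area total integrated absorbance distributed over the bands.
#' @return A [spectrum()] of kind `"ftir"`.
#' @export
gen_amide1_spectrum <- function(band_table,
                                grid = seq(1595, 1705, by = 0.5),
                                noise_sd = 0, seed = NULL, total_area = 1) {
  stopifnot(is.data.frame(band_table),
            all(c("center", "fwhm", "area") %in% names(band_table)))
  if (abs(sum(band_table$area) - 1) > 1e-9)
    stop_input("band area fractions must sum to 1")
  if (any(band_table$center < 1595 | band_table$center > 1705))
    stop_input("band centers must lie within 1595-1705 cm^-1")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  v <- rep(0, length(grid))
  for (i in seq_len(nrow(band_table))) {
    v <- v + gauss_area(grid, band_table$center[i], band_table$fwhm[i],
                        band_table$area[i] * total_area)
  }
  with_seed(seed, {
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    spectrum(grid, v, kind = "ftir")
  })
}

#' Synthetic fluorescence emission spectra (ANS and pyrene probes)
#'
#' ANS bound to hydrophobic protein surfaces emits at 470 nm, free ANS at
#' 520 nm. Pyrene emits two vibronic bands placed at the centers of the I1
#' (371-376 nm) and I3 (398-403 nm) integration windows, with amplitude
#' ratio set by `i1_i3`, so [pyrene_ratio()] round-trips exactly at zero
#' noise.
#'
#' @param probe `"ans_bound"`, `"ans_free"` or `"pyrene"`.
#' @param grid wavelength grid (nm): must cover 420-600 nm for ANS, 350-420
#'   nm for pyrene.
#' @param i1_i3 target I1/I3 intensity ratio (pyrene only).
#' @param amplitude peak-scale intensity in counts.
#' @param noise_sd additive Gaussian noise sd (counts).
#' @param seed optional RNG seed.
#' @return A [spectrum()] of kind `"fluorescence"`.
#' @export
gen_emission_spectrum <- function(probe = c("ans_bound", "ans_free", "pyrene"),
                                  grid = NULL, i1_i3 = 1.5,
                                  amplitude = 1000, noise_sd = 0,
                                  seed = NULL) {
  probe <- match.arg(probe)
  if (is.null(grid)) {
    grid <- if (probe == "pyrene") seq(350, 420, by = 1) else seq(420, 600, by = 1)
  }
  grid <- as.numeric(grid)
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  if (probe %in% c("ans_bound", "ans_free")) {
    if (min(grid) > 420 || max(grid) < 600)
      stop_input("ANS emission grid must cover 420-600 nm")
    v <- switch(probe,
      ans_bound = gauss_height(grid, 470, 60, amplitude),
      ans_free  = gauss_height(grid, 520, 80, 0.6 * amplitude))
  } else {
    if (min(grid) > 350 || max(grid) < 420)
      stop_input("pyrene emission grid must cover 350-420 nm")
    if (i1_i3 <= 0) stop_input("i1_i3 must be > 0")
    # bands at the window centers; window means then scale exactly with the
    # amplitudes, making the target ratio exact on symmetric grids
    v <- gauss_height(grid, 373.5, 6, amplitude * i1_i3) +
         gauss_height(grid, 400.5, 6, amplitude)
  }
  with_seed(seed, {
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    spectrum(grid, v, kind = "fluorescence")
  })
}
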