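#' SDS-PAGE lane intensity profile
#'
#' One-dimensional densitometry trace: pixel intensity as a function of lane
#' position. Intensities are band-positive (bands appear as peaks), i.e. the
#' gel image is assumed already inverted relative to a Coomassie scan.
#'
#' @param positions increasing pixel indices.
#' @param intensities non-negative intensities, same length.
#' @return An object of class `lane_profile`.
#' @export
lane_profile <- function(positions, intensities) {
  positions <- as.numeric(positions)
  intensities <- as.numeric(intensities)
  if (length(positions) != length(intensities))
    stop_input("positions and intensities must have equal length")
  if (any(diff(positions) <= 0))
    stop_input("positions must be strictly increasing")
  if (any(intensities < 0))
    stop_input("intensities must be non-negative")
  structure(list(positions = positions, intensities = intensities),
            class = "lane_profile")
}

#' Synthetic gel lanes with a calibration ladder
#'
#' Generates a ladder lane (Gaussian bands at the positions of known
#' molecular-weight standards) and a sample lane (smear mixture of
#' components) under one shared monotone log10(MW) -> pixel-position map,
#' emulating densitometry of an SDS-PAGE gel. Migration distance increases
#' as molecular weight decreases.
#'
#' @param ladder_mws ladder standards (kDa), strictly decreasing along the
#'   migration direction; at least 3.
#' @param sample_components data frame with columns `mw` (kDa), `amount`
#'   (relative weight) and `spread` (smear sd in log10(MW) units); may have
#'   zero rows for a blank lane.
#' @param lane_length_px lane length in pixels.
#' @param band_sd_px intrinsic band width (pixels).
#' @param noise_sd additive intensity noise sd.
#' @param seed optional RNG seed.
#' @return List with elements `ladder` and `sample`, both [lane_profile()].
#' @export
gen_gel_lanes <- function(ladder_mws, sample_components,
                          lane_length_px = 500, band_sd_px = 5,
                          noise_sd = 0, seed = NULL) {
  ladder_mws <- as.numeric(ladder_mws)
  if (length(ladder_mws) < 3)
    stop_input("need at least 3 ladder bands for calibration")
  if (any(diff(ladder_mws) >= 0))
    stop_input("ladder_mws must be strictly decreasing along migration")
  stopifnot(is.data.frame(sample_components))
  if (nrow(sample_components) > 0 &&
      !all(c("mw", "amount", "spread") %in% names(sample_components)))
    stop_input("sample_components needs columns mw, amount, spread")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")

  L <- lane_length_px
  pos <- seq_len(L)
  lM <- log10(ladder_mws)
  p_lo <- 0.08 * L; p_hi <- 0.92 * L
  slope_px <- (p_hi - p_lo) / (max(lM) - min(lM))  # px per log10(kDa)
  pos_of_mw <- function(m) p_lo + (max(lM) - log10(m)) * slope_px

  ladder_v <- rep(0, L)
  for (m in ladder_mws)
    ladder_v <- ladder_v + exp(-(pos - pos_of_mw(m))^2 / (2 * band_sd_px^2))

  sample_v <- rep(0, L)
  if (nrow(sample_components) > 0) {
    for (i in seq_len(nrow(sample_components))) {
      m <- sample_components$mw[i]
      amt <- sample_components$amount[i]
      sd_px <- sqrt(band_sd_px^2 +
                      (sample_components$spread[i] * slope_px)^2)
      sample_v <- sample_v +
        amt * exp(-(pos - pos_of_mw(m))^2 / (2 * sd_px^2))
    }
  }
  with_seed(seed, {
    if (noise_sd > 0) {
      ladder_v <- pmax(0, ladder_v + stats::rnorm(L, 0, noise_sd))
      sample_v <- pmax(0, sample_v + stats::rnorm(L, 0, noise_sd))
    }
    list(ladder = lane_profile(pos, ladder_v),
         sample = lane_profile(pos, sample_v))
  })
}
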