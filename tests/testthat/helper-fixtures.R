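# Shared fixture builders. All synthetic data are generated in code at test
# time; seeds are fixed per test.

cd_grid <- function() 185:260

# Amide I band table with a prescribed beta area fraction among the
# non-side-chain bands (side-chain band carries a fixed 4% of total area).
amide_band_table <- function(beta) {
  sc <- 0.04
  nonsc <- 1 - sc
  data.frame(
    center = c(1605, 1620, 1643, 1655, 1678, 1698),
    fwhm   = c(14, 18, 16, 14, 22, 10),
    area   = c(sc,
               nonsc * (beta - 0.08),
               nonsc * (1 - beta) * 0.45,
               nonsc * (1 - beta) * 0.25,
               nonsc * (1 - beta) * 0.30,
               nonsc * 0.08)
  )
}

# HiMark-style protein standard ladder (kDa), decreasing along migration.
ladder_mws <- function() c(460, 268, 238, 171, 117, 71, 55, 41, 31)

# Two-slope pyrene I1/I3 model in log10 concentration, continuous at the
# breakpoint.
pyrene_series_model <- function(conc, break_mgml = 1, slope_left = -0.3,
                                slope_right = -0.05, ratio_at_break = 1.45) {
  x <- log10(conc)
  xb <- log10(break_mgml)
  ratio_at_break + ifelse(x < xb, slope_left * (x - xb),
                          slope_right * (x - xb))
}
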