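#!/usr/bin/env Rscript
# Generates the synthetic raw measurements used throughout the analysis:
# a seeded CD time series per nanowhisker concentration, Amide I spectra at
# the three patterned-film compositions, a pyrene concentration series,
# width and modulus samples, force curves, and a pair of gel lanes.
# Everything is seeded, so re-running reproduces results/ byte-for-byte.

suppressMessages(library(silkcryst))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed0 <- 20260924L

## CD time series at four seed concentrations: lag falls with log10(conc),
## rate rises linearly, emulating the templated-assembly scaling laws.
seed_conc <- c(1, 2.5, 5, 7.5)  # wt% peptide relative to silk
times <- seq(0, 48, by = 1)     # h
for (i in seq_along(seed_conc)) {
  cc <- seed_conc[i]
  k <- 0.12 + 0.05 * cc
  t_lag <- 16 - 9 * log10(cc)
  p <- kinetic_params("logistic", k = k, t_half = t_lag + 1 / (2 * k))
  specs <- gen_cd_timeseries(p, times, noise_sd = 0.15, seed = seed0 + i)
  for (j in seq_along(times)) {
    write_spectrum_csv(specs[[j]], file.path(out, sprintf(
      "cd_conc%.1f_t%03d.csv", cc, times[j])))
  }
}
writeLines(sprintf("%.1f", seed_conc), file.path(out, "seed_conc_pct.txt"))

## Amide I spectra for the three compositions (beta area fractions
## 0.68 / 0.51 / 0.16: seeded-patterned, alternative-seed, unpatterned).
beta_bands <- function(beta) {
  sc <- 0.04; nonsc <- 1 - sc
  data.frame(center = c(1605, 1620, 1643, 1655, 1678, 1698),
             fwhm = c(14, 18, 16, 14, 22, 10),
             area = c(sc, nonsc * (beta - 0.08),
                      nonsc * (1 - beta) * 0.45,
                      nonsc * (1 - beta) * 0.25,
                      nonsc * (1 - beta) * 0.30,
                      nonsc * 0.08))
}
for (b in c(0.68, 0.51, 0.16)) {
  s <- gen_amide1_spectrum(beta_bands(b), noise_sd = 2e-4,
                           seed = seed0 + round(100 * b))
  write_spectrum_csv(s, file.path(out, sprintf("amide1_beta%02.0f.csv",
                                               100 * b)))
}

## Pyrene I1/I3 concentration series with a break at 1 mg/ml.
cc <- 10^seq(-2, 1, length.out = 12)
x <- log10(cc)
set.seed(seed0 + 8)
ratio <- 1.45 + ifelse(x < 0, -0.3 * x, -0.05 * x) + rnorm(12, 0, 0.01)
utils::write.csv(data.frame(conc_mg_ml = cc, i1_i3 = ratio),
                 file.path(out, "pyrene_series.csv"), row.names = FALSE)

## Width samples: nanowhisker seeds (19 +/- 4 nm) and 1-h nanocomplexes
## (34 +/- 9 nm), ~160 measurements each.
utils::write.csv(data.frame(
  width_nm = c(gen_normal_sample(19, 4, 160, seed = seed0 + 19),
               gen_normal_sample(34, 9, 160, seed = seed0 + 34)),
  stage = rep(c("seed", "1h"), each = 160)),
  file.path(out, "widths.csv"), row.names = FALSE)

## AM-FM modulus map sample (10,000 px, 4.18 +/- 0.71 GPa, log-normal).
utils::write.csv(data.frame(
  modulus_gpa = gen_lognormal_sample(4.18, 0.71, 1e4, seed = seed0 + 41)),
  file.path(out, "amfm_moduli.csv"), row.names = FALSE)

## 216 gel-indentation force curves (true E ~ N(5.96, 0.48) MPa).
e_true <- gen_normal_sample(5.96e6, 0.48e6, 216, seed = seed0 + 59)
utils::write.csv(data.frame(curve = seq_along(e_true), E_true_pa = e_true),
                 file.path(out, "gel_moduli_true.csv"), row.names = FALSE)
# curves themselves are regenerated on demand in 04_nanomech.R (they are
# large); only the per-curve ground truth is persisted here

## SDS-PAGE lanes: ladder plus a native-silk lane (single ~390 kDa band)
## and a degummed-silk smear.
ladder <- c(460, 268, 238, 171, 117, 71, 55, 41, 31)
native <- gen_gel_lanes(ladder, data.frame(mw = 390, amount = 1,
                                           spread = 0.02),
                        noise_sd = 0.002, seed = seed0 + 39)
degummed <- gen_gel_lanes(ladder, data.frame(
  mw = c(250, 120, 60), amount = c(0.5, 1, 0.7),
  spread = c(0.12, 0.15, 0.12)), noise_sd = 0.002, seed = seed0 + 60)
for (nm in c("ladder", "sample")) {
  utils::write.csv(data.frame(position_px = native[[nm]]$positions,
                              intensity = native[[nm]]$intensities),
                   file.path(out, sprintf("gel_native_%s.csv", nm)),
                   row.names = FALSE)
}
utils::write.csv(data.frame(position_px = degummed$sample$positions,
                            intensity = degummed$sample$intensities),
                 file.path(out, "gel_degummed_sample.csv"),
                 row.names = FALSE)

cat("synthetic raw data written to", out, "\n")
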