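#!/usr/bin/env Rscript
# Morphometry and nanomechanics: width-histogram normal fits with the
# stage comparison, AM-FM log-normal modulus statistics, and the bulk-gel
# modulus pipeline (per-curve Hertz fits -> Gaussian summary), with JKR
# and Oliver-Pharr cross-checks on a representative curve.

suppressMessages(library(silkcryst))
datadir <- "results/data"
stopifnot(dir.exists(datadir))
seed0 <- 20260924L

## Widths
w <- utils::read.csv(file.path(datadir, "widths.csv"))
f_seed <- fit_normal(w$width_nm[w$stage == "seed"], stage = "seed")
f_1h <- fit_normal(w$width_nm[w$stage == "1h"], stage = "1h")
cmp <- compare_stages(f_seed, f_1h)
utils::write.csv(data.frame(
  stage = c("seed", "1h"), mean_nm = c(f_seed$mean, f_1h$mean),
  sd_nm = c(f_seed$sd, f_1h$sd), n = c(f_seed$n, f_1h$n)),
  "results/width_fits.csv", row.names = FALSE)
cat(sprintf("widths: seed %.1f +/- %.1f nm, 1 h %.1f +/- %.1f nm\n",
            f_seed$mean, f_seed$sd, f_1h$mean, f_1h$sd))
cat(sprintf("thickening in the first hour: +%.1f nm (Welch p = %.2g)\n",
            cmp$delta_mean, cmp$p))

## AM-FM moduli
e <- utils::read.csv(file.path(datadir, "amfm_moduli.csv"))$modulus_gpa
fl <- fit_lognormal(e, source = "amfm")
utils::write.csv(data.frame(mean_gpa = fl$mean, sd_gpa = fl$sd,
                            mu_log = fl$mu_log, sigma_log = fl$sigma_log,
                            n = fl$n),
                 "results/amfm_lognormal.csv", row.names = FALSE)
cat(sprintf("AM-FM moduli: %.2f +/- %.2f GPa (log-normal, n = %d)\n",
            fl$mean, fl$sd, fl$n))

## Bulk-gel pipeline: 216 Hertz-fitted force curves
gel <- utils::read.csv(file.path(datadir, "gel_moduli_true.csv"))
R <- 0.3e-6; nu <- 0.33; depth <- 100e-9
e_hat <- vapply(seq_len(nrow(gel)), function(i) {
  E <- gel$E_true_pa[i]
  fmax <- (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * depth^1.5
  fc <- gen_force_curve(E, R, nu, depth, noise_sd = 0.02 * fmax,
                        n_points = 100, seed = seed0 + 1000L + i)
  hertz_fit(fc)
}, numeric(1))
fg <- fit_gaussian_moduli(e_hat)
utils::write.csv(data.frame(mean_mpa = fg$mean / 1e6, sd_mpa = fg$sd / 1e6,
                            n = fg$n),
                 "results/gel_modulus.csv", row.names = FALSE)
cat(sprintf("gel modulus (Hertz, 216 curves): %.2f +/- %.2f MPa\n",
            fg$mean / 1e6, fg$sd / 1e6))

## Model cross-check on one representative adhesive curve
E_ref <- median(gel$E_true_pa)
fj <- gen_force_curve(E_ref, R, nu, depth, model = "jkr",
                      work_adhesion = 0.02)
jk <- jkr_fit(fj)
fo <- gen_force_curve(E_ref, 1e-6, nu, 20e-9, model = "jkr",
                      work_adhesion = 0)
eo <- oliver_pharr_fit(fo)
cat(sprintf(
  "cross-check at E = %.2f MPa: JKR %.2f MPa (w = %.3f J/m^2), O-P %.2f MPa\n",
  E_ref / 1e6, jk$E / 1e6, jk$work_adhesion, eo / 1e6))
utils::write.csv(data.frame(model = c("hertz_ref", "jkr", "oliver_pharr"),
                            E_mpa = c(E_ref, jk$E, eo) / 1e6),
                 "results/contact_model_crosscheck.csv", row.names = FALSE)
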