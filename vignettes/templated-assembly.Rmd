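---
title: "Quantifying templated crystallization of silk fibroin: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying templated crystallization of silk fibroin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkcryst)
```

## Scope

`silkcryst` implements the quantitative machinery used to characterize
seeded ("templated") crystallization of silk fibroin on beta-sheet peptide
nanowhiskers: conversion of time-series circular-dichroism (CD) spectra
into assembly fraction-completion traces, kinetic model fitting,
secondary-structure quantification from FTIR Amide I bands, fluorescent
probe analyses, morphometric and nanomechanical distribution fitting,
contact-mechanics inversion of AFM force curves, and SDS-PAGE densitometry.
No instrument data ships with the package: a seeded synthetic-data module
generates every raw-data shape the pipeline consumes, so each analysis
stage is testable end to end and every reported number in the `analysis/`
workflow is reproducible from code.

## Two-state CD model and assembly kinetics

The central assumption is that each CD spectrum observed during assembly is
a convex combination of two basis states: the initial unordered
(random-coil) spectrum and the final beta-sheet spectrum at equilibrium,

$$S_t = (1 - y_t)\,S_0 + y_t\,S_\infty,$$

where $y_t \in [0, 1]$ is the fraction completion. `decompose_two_state()`
estimates $y_t$ by bounded least squares with a single mixing weight. The
bound is a deliberate choice: an unconstrained two-coefficient fit followed
by normalization can return fractions outside $[0,1]$ for noisy spectra and
weakens the two-state interpretation, whereas the single bounded parameter
yields a direct fraction. The closed-form projection of the unconstrained
minimizer onto $[0,1]$ is exact for this one-parameter problem; a
brute-force grid search over $f \in \{0, 0.001, \dots, 1\}$ is kept in the
test suite as an independent oracle. By default the equilibrium basis is
the last time point of the series, matching the experimental convention
that equilibrium is reached when the spectrum stops changing; an explicit
equilibrium spectrum overrides this.

Fraction-completion traces are fit with the empirical logistic model

$$y(t) = \frac{1}{1 + e^{-k (t - t_{0.5})}},$$

with growth rate $k$ (1/h) and midpoint $t_{0.5}$ (h), and the lag time is
derived as

$$t_\mathrm{lag} = t_{0.5} - \frac{1}{2k},$$

the intercept of the midpoint tangent with the baseline. The identity
$t_\mathrm{lag} + 1/(2k) = t_{0.5}$ holds to machine precision for every
fit because `t_lag` is computed from the fitted $(k, t_{0.5})$, never
refit. Initialization is deterministic: $t_{0.5}$ starts at the first
linear-interpolated crossing of $y = 0.5$ and $k$ at $4/(t_{90} - t_{10})$.
A trace whose fractions do not span at least $[0.2, 0.8]$ is flagged
non-converged, since the plateaus are then unidentifiable. Fractions are
never clamped before fitting: clamping truncates the noise distribution
near 0 and 1 and biases both parameters.

The alternative Avrami (JMAK) phase-transformation model is implemented in
its canonical form

$$y(t) = 1 - e^{-(K t)^n},$$

with the exponent $n$ interpreted as the growth dimensionality and
restricted to the integers 1-4. For each candidate $n$ the rate constant
$K$ is fit by one-dimensional least squares over $\log K$ (a smooth,
unimodal profile), and the $n$ minimizing the residual sum of squares is
selected, with the full per-$n$ RSS table reported. The exact JMAK variant
used in the original kinetics work is not printed anywhere we could
verify, so the canonical form is a package design decision. Note that when
the selection is run on data generated from a *logistic* truth, the
selected $n$ reflects the best JMAK approximation to a different curve
family and can legitimately vary with the sampling window; dimensionality
conclusions should only be drawn from traces the JMAK family describes
well (comparable per-$n$ RSS magnitudes are the diagnostic).

Seed-concentration scaling is quantified by ordinary least squares of the
fitted lag times on $\log_{10}$(seed concentration) and of the fitted
growth rates on seed concentration — the two empirical laws that
characterize templated assembly (lag falls log-linearly, rate rises
linearly).

## Synthetic data: what it emulates and what it does not

Each generator is a pure function of its parameters and an integer seed;
identical inputs give bit-identical outputs, and the caller's RNG state is
restored afterwards. Defaults encode the study conditions: CD spectra on
185-260 nm, beta-sheet basis bands at +196/-218 nm, unordered minimum at
198 nm (Gaussian bands, FWHM 12/16/14 nm — minimal shapes that reproduce
the printed extrema); Amide I mixtures on 1595-1705 cm^-1; ANS emission
peaks at 470 nm (bound) and 520 nm (free); pyrene vibronic bands placed at
the centers of the I1 (371-376 nm) and I3 (398-403 nm) windows so the
target ratio is exact on a symmetric grid; width samples of n = 160 from
N(34, 9^2) nm for the 1-h nanocomplexes (seeds: N(19, 4^2)); AM-FM modulus
samples of n = 10,000 with arithmetic mean 4.18 GPa and sd 0.71 GPa
(log-normal); 216 bulk-gel force curves with true moduli from
N(5.96, 0.48^2) MPa on a 0.3 um bead at 100 nm depth and 2% force noise;
and gel lanes under a log-linear migration map with a 9-band ladder.

Noise is additive i.i.d. Gaussian everywhere — the simplest defensible
model. Real spectra carry correlated baseline drift, detector saturation
and cuvette artifacts that the generators do not emulate; real force
curves carry drift, hydrodynamic drag and non-ideal contact geometry.
Passing the round-trip tests therefore demonstrates correctness of the
estimators under the stated noise model, not robustness to every
instrument pathology. Parameter-recovery tolerances in the test suite are
CLT bounds ($3\sigma/\sqrt{n}$) or Monte-Carlo-established margins, not
tuned numbers.

## Amide I quantification

Fourier self-deconvolution (FSD) is implemented as Fourier-domain line
narrowing: the interferogram (the FFT of the spectrum) is multiplied by
$\exp(2\pi\gamma(1 - 1/K)|x|)$, where $\gamma$ is half the assumed
Lorentzian component FWHM (default 25 cm^-1) and $K \ge 1$ the enhancement
factor (default 2). This maps Lorentzian components of FWHM $2\gamma$ to
Lorentzians narrower by $K$, and is the exact identity at $K = 1$. Two
linear, parameter-only edge treatments precede the transform (subtraction
of the straight line through the window endpoints, mirror extension), and
a triangular-squared apodization truncated where the exponential gain
reaches 10^4 caps noise amplification. Because every factor is independent
of the data, the whole operation is linear in the spectrum — a property
the tests verify, along with agreement with a literal $O(N^2)$ DFT oracle.

Band quantification deliberately separates detection from integration:
`amide1_pipeline()` uses the FSD-resolved extrema to locate component
bands, then fits the Gaussian mixture to the *original* spectrum. Line
narrowing does not conserve areas band-wise (narrow components gain
relative intensity because the exponential weight amplifies their
high-frequency content), so integrating the deconvolved spectrum
systematically inflates sharp bands — for beta-sheet components, an
overestimate of 10 percentage points or more on realistic mixtures. Fitting
the raw spectrum with FSD-informed centers avoids that bias; the
assignment windows (side chain 1595-1609, beta-sheet 1610-1637, random
coil 1638-1648, alpha-helix 1649-1662, turns 1663-1694, high-frequency
beta 1695-1705 cm^-1) confine each center during optimization. The
beta-sheet percentage is the combined beta area over the total
non-side-chain area; side-chain absorption is excluded from the
denominator because it is not secondary structure. Fractions sum to 100 by
construction; convergence is reported, never silently assumed.

## Probes

The pyrene I1/I3 ratio is the arithmetic mean over the closed 371-376 nm
window divided by the mean over 398-403 nm, the literal reading of
"intensity averaged over" each band. The micellization breakpoint is found
by a continuous two-segment piecewise-linear fit in
($\log_{10} c$, ratio), with the breakpoint searched exhaustively over the
midpoints between consecutive observed log-concentrations. Continuity is
enforced because the underlying phenomenon is a slope change, not a jump;
the candidate-midpoint grid is deterministic and exhaustive at the
resolution of the data, which also makes the estimate exactly equivariant
under unit rescaling. A breakpoint between observed concentrations can
only be located to within the local candidate spacing — on a 12-point
series over 0.01-10 mg/ml this is about a quarter decade, which is why the
recovery tolerance is a factor of two rather than a percentage.

## Nanomechanics

All three contact models treat the tip as a rigid sphere
($E_r = E/(1-\nu^2)$, tip modulus effectively infinite against MPa-GPa
samples) with $\nu = 0.33$ as the default Poisson ratio.

* **Hertz**: $F = \tfrac{4}{3} E_r \sqrt{R}\,\delta^{3/2}$, linear in
  $\delta^{3/2}$, solved in closed form over the contact region. Contact
  is detected (when pre-contact data are present) as the first force
  exceeding three pre-contact noise standard deviations, then re-zeroed.
* **JKR**: contact radius
  $a^3 = (R/\bar K)\big(F + 3\pi w R + \sqrt{6\pi w R F + (3\pi w R)^2}\big)$
  with $\bar K = \tfrac{4}{3}E/(1-\nu^2)$, indentation
  $\delta = a^2/R - \sqrt{2\pi w a/\bar K}$. The fit minimizes indentation
  residuals as a function of force over $(\log E, \log w)$; the pull-off
  force is $-\tfrac{3}{2}\pi w R$ (a closed-form identity the tests check
  independently), and $w = 0$ reduces exactly to Hertz.
* **Oliver-Pharr**: power-law fit $F = \alpha(\delta - \delta_f)^m$ on the
  20-95% unload window (dimensionless rescaling for conditioning),
  stiffness $S$ at peak, contact depth $h_c = \delta_\max - 0.75
  F_\max/S$, spherical area $A = \pi(2 R h_c - h_c^2)$,
  $E_r = S\sqrt{\pi}/(2\sqrt{A})$.

On noiseless Hertz-generated curves the three models agree to within 2%
when $\delta_\max \ll R$. This is a real geometric restriction, not a
numerical artifact: the spherical-area Oliver-Pharr estimate carries an
intrinsic $(1 - \delta_\max/4R)^{-1/2}$ factor relative to Hertz, about 4%
at $\delta_\max/R = 1/3$ (a 100 nm indent on a 0.3 um bead) and under 1%
at $\delta_\max/R = 0.02$. Cross-model agreement checks therefore use
shallow-contact geometry (20 nm on a 1 um sphere); the bulk-gel modulus
pipeline uses Hertz fits, where no such restriction applies.

Modulus histograms are summarized by a maximum-likelihood log-normal fit
on log values, reported as the arithmetic mean and standard deviation of
the fitted distribution (the AM-FM convention), with the log-space
parameters alongside; the moment identities link the two
parameterizations exactly. Width histograms use the sample mean and the
$n-1$ standard deviation — the unbiased convention, applied consistently
to both normal and log-normal fits.

## Gel densitometry

The ladder calibration detects band peaks (local maxima of the lightly
smoothed profile above 20% of the maximum, with the count required to
match the number of standards) and interpolates $\log_{10}$(MW) against
pixel position piecewise-linearly, extrapolating linearly at the ends —
the classic Ferguson-style calibration with no extra parameters. Lane
intensities are min-max normalized to $[0,1]$ and pixels below 5% of the
maximum are treated as background. The package takes band-positive
(inverted) profiles as input: the conventional gel scan has dark bands on
a bright background, and the inversion step belongs to image export, not
to this 1-D analysis. Intensity is interpreted as weight (mass) fraction,
so with the Jacobian-corrected density $w(M)$,
$M_w = \int M\,w(M)\,dM$, $M_n = \big(\int w(M)/M\,dM\big)^{-1}$, and
$\mathrm{PDI} = M_w/M_n \ge 1$ with equality only for a monodisperse
sample — the standard polymer convention.

## Problem sizes and determinism

The analysis workflow and the acceptance script run the study-sized
problems directly: 49 spectra per CD series, 221-point Amide I spectra,
n = 160 width samples, n = 10,000 modulus samples, 216 force curves of 100
points each, 500-pixel gel lanes. All stochastic stages take explicit
seeds and record them; re-running any script reproduces its outputs
exactly.

## Known limitations

* The two-state CD model cannot represent intermediate conformations; a
  three-state trajectory projects onto the nearest two-state mixture.
* JMAK dimensionality selection assumes the JMAK family fits well;
  model-family mismatch shows up as uniformly poor per-$n$ RSS.
* FSD band detection assumes approximately Lorentzian-to-Gaussian band
  shapes within the Amide I window; strongly non-Gaussian components bias
  the mixture fit.
* The JKR inversion uses the force-controlled loading branch; near
  pull-off under displacement control the unstable branch is not modelled.
* Gel analysis starts from a 1-D lane profile; lane finding, rolling-ball
  background subtraction and other image-level corrections are out of
  scope.
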