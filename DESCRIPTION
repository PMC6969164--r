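Package: silkcryst
Title: Kinetics, Spectroscopy and Nanomechanics of Templated Silk Fibroin Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis machinery for seeded ("templated") crystallization of
    silk fibroin on beta-sheet peptide nanowhiskers. Converts time-series
    circular-dichroism spectra into assembly fraction-completion traces via a
    two-state spectral model; fits logistic kinetics with lag-time extraction
    and Avrami (JMAK) kinetics with growth-dimensionality selection; analyses
    seed-concentration scaling laws; quantifies beta-sheet content from FTIR
    Amide I bands by Fourier self-deconvolution and Gaussian band fitting;
    locates fluorescent-probe emission peaks and pyrene I1/I3 micellization
    breakpoints; fits fibril-width and modulus distributions; inverts AFM
    force-indentation curves with Hertz, JKR and Oliver-Pharr contact models;
    and derives molecular-weight distributions from SDS-PAGE densitometry.
    Includes seeded synthetic-data generators for every raw-data shape so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
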