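Package: isoturn
Title: Protein Turnover Rate Constants from Stable Isotope Labeling
    Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures first-order protein degradation rate constants (k_deg)
    from metabolic stable-isotope labeling time courses acquired by mass
    spectrometry, supporting both heavy-water (2H2O) and amino-acid (13C6
    lysine) label chemistries. Integrates MS1 isotopomer chromatograms from
    centroided mzML files for peptides identified in Percolator-style search
    result tables, converts isotopomer areas to relative isotope abundance
    time series, and fits one-compartment, two-compartment and
    precursor-convolution kinetic models with error propagation and
    AIC-based model selection. Provides strategies for estimating precursor
    enrichment kinetics (including mass isotopomer distribution analysis of
    dilysine peptides and calibration against a heavy-water reference),
    peptide quality filters, four protein-level aggregation methods, and a
    synthetic-experiment generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mzR,
    minpack.lm,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
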