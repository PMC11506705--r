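Package: h1prm
Title: Design and Quantification Toolkit for Targeted Proteomics of Histone
    H1 Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing parallel reaction monitoring
    (PRM) assays that quantify near-identical protein families, developed
    around the seven somatic histone H1 subtypes. Performs in-silico trypsin
    and Glu-C digestion with proteotypic (unique-peptide) candidate selection,
    monoisotopic and stable-isotope-label mass arithmetic for precursors and
    b/y fragment ions, calibration-curve fitting with limits of detection and
    quantification, light/heavy ratio quantification with oxidation and
    missed-cleavage corrections, H1-complement (subtype proportion) profiles
    with gel-band reconciliation, and small-cohort biomarker statistics
    (exact Mann-Whitney rank-biserial critical values, ROC/Youden, Matthews
    correlation, correlation-distance clustering, PCA). Includes
    ground-truth-known simulators for every input format so the full pipeline
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
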