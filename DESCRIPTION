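Package: adductscreen
Title: Adduct Discovery in MALDI Mass Spectrometry Imaging via Mass
    Differences and Spatial Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies metabolite-matrix and alkali-metal
    adducts in high-mass-resolution MALDI mass spectrometry imaging (MSI)
    data.  Computes mass differences between all pairs of peaks, matches
    them against an exact-mass adduct registry under a ppm-propagated
    tolerance, subtracts matrix-blank peaks, and screens false positives
    with per-pixel Pearson correlation tests (Bonferroni, Storey q-values,
    correlation-coefficient cutoffs).  Includes imzML and CSV
    intensity-matrix input/output, dataset-conditioning filters, a seeded
    synthetic MSI generator with ground truth, reporting utilities, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
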