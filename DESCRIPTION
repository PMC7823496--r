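Package: eprdyn
Title: Spin-Label EPR Analysis of Membrane Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing nitroxide spin-label electron paramagnetic
    resonance (EPR) spectra of biological membranes. Simulates first-derivative
    fast-motion (three-line) and anisotropic (axially split) nitroxide spectra
    with analytically known ground truth, extracts the standard spectral
    parameters (outer and inner hyperfine splittings, central linewidth and the
    three line amplitudes), and converts them into the dynamic orientational
    order parameter S and the rotational correlation times tau2B and tau2C.
    Also provides chlorophyll and carotenoid quantification from 80 percent
    acetone extract absorbances, fatty-acid unsaturation summaries from GC-FAME
    mole-percent tables, and per-temperature two-sample comparisons for
    genotype by acclimation-temperature series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
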