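Package: scoterg
Title: Scotopic Electroretinogram Analysis and Retinal Bioenergetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature extraction for murine scotopic full-field
    electroretinograms (a-wave, b-wave, positive scotopic threshold
    response), isolation of oscillatory potentials by hard spectral
    band-pass filtering (FFT mask, 65-300 Hz) with wavelet
    quantification, Naka-Rushton intensity-response fitting to estimate
    the maximum rod-driven b-wave response (Bmax), stimulus calibration
    to photoisomerizations per rod, derivation of mitochondrial
    respiration parameters (basal, maximal, spare, non-mitochondrial)
    from three-phase extracellular-flux oxygen-consumption traces, and
    the accompanying group statistics: two-sample t-tests from raw data
    or published mean/SEM/n summaries, split-plot (mixed) ANOVA with
    Greenhouse-Geisser correction, and simple main effects. A synthetic
    data module generates ground-truthed ERG epochs, OCR traces, and
    cohort tables so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
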