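Package: renoperf
Title: Quantitative Perfusion and Biodistribution Analysis for
    Intra-Arterial Microcapsule Delivery
Version: 0.1.0
Authors@R:
    person("Renoperf", "Developers", email = "renoperf@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for preclinical studies of microcapsule
    delivery through the renal artery. Implements laser speckle contrast
    imaging (LSCI) processing from raw speckle frames to baseline-normalized
    percent blood flow with a reversibility/safety classification,
    optoacoustic (RSOM) frequency-band intensity and alteration analysis
    with depth-resolved band profiles, and two percent-injected-dose (%ID)
    quantifications: imaging-based organ %ID with area-scaled
    autofluorescence correction and calibration-based dye quantification
    from plate-reader emission spectra. Every input can be generated
    synthetically with known ground truth (dynamic fully developed speckle
    with controllable decorrelation time, organ fluorescence tables,
    band-limited acoustic signals, linear-response fluorimetry plates), so
    the whole chain is testable against analytic and generator oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
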