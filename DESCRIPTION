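Package: meibumr
Title: Quantitative Lipidomics and Thermotropic Analysis of Meibum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative profiling of Meibomian gland secretions
    (meibum) by positive-mode APCI liquid chromatography / high-resolution
    mass spectrometry, and for thermotropic analysis of meibum melting.
    Provides an exact-mass registry of meibum lipid species (cholesterol,
    cholesteryl esters, wax esters, triacylglycerols and related classes)
    with adduct and fragment ion channels; extracted-ion-chromatogram (EIC)
    peak detection and integration; response-factor calibration against an
    equimolar lipid standard mixture; cholesterol-to-cholesteryl-ester
    ratios, fatty-acid chain-length profiles and lipid class balances with
    group statistics; a two-transition Hill model of birefringence melting
    curves with overflow-safe evaluation, spline-based transition detection
    and constrained nonlinear fitting; eye-opening ellipticity metrics; and
    a synthetic-data generator (chromatograms with genotype presets,
    melting curves) so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mzR,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
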