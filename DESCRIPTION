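Package: xrdmatch
Title: Forensic Substance Identification from X-Ray Powder Diffraction Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for screening seized drug samples by X-ray powder
    diffraction (XRPD). Reads two-column diffractograms, preprocesses them
    (iterative polynomial background subtraction, Savitzky-Golay smoothing,
    Rachinger-type K-alpha2 stripping, normalization), detects and matches
    diffraction peaks against a reference phase library, and quantifies
    whole-pattern similarity with a cross-correlation score computed on
    squared, normalized patterns. Includes a pseudo-Voigt diffractogram
    simulator (Cu K-alpha doublet, preferred-orientation-style intensity
    perturbation, adulterant mixtures, Poisson counting noise) used as the
    test substrate, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
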