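Package: cochleametrics
Title: Quantitative Analysis of Cochlear Calcium, Morphology, Stereocilia
    Motion and Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studies of metabolic (lateral-wall)
    hearing loss in the cochlea. Implements fluorescence correlation
    spectroscopy (multi-tau autocorrelation, three-dimensional anomalous
    diffusion model fitting, background-corrected molecular brightness),
    organ of Corti and tectorial membrane morphometry from regions of
    interest (minimal gap, pixel-count areas, organ width, per-cochlea
    averaging), phase-stamped confocal kinematics (phase binning, subpixel
    optical flow, stereocilia deflection), evoked-potential analysis
    (cochlear microphonic amplitude and phase, summating potential, tuning
    curves, input-output functions and thresholds, distortion-product
    otoacoustic emissions), and the accompanying statistics layer
    (compound-symmetry generalised least squares, one-way ANOVA with
    Tukey-Kramer post-hoc tests, rank tests, threshold regression).
    Includes synthetic-data generators with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nlme,
    minpack.lm,
    MASS,
    signal,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
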