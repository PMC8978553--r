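Package: msdrift
Title: Mean-Shift Drift Correction for Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and corrects lateral (2D) and volumetric (3D) sample
    drift in single-molecule localization microscopy (SMLM/PALM/STORM) data
    using an iterative mean-shift peak finder on pairwise displacements
    between temporal bins of localizations. Pairwise shift estimates between
    all bin pairs are combined by error-weighted redundant linear least
    squares into a drift trajectory with confidence intervals, which is then
    applied to the localization table. Includes a benchmark simulator
    (circular test cell in 2D, cylindrical volume in 3D, known shifts and
    drift curves), a center-of-mass baseline, and Fourier ring correlation
    (FRC) resolution estimation for scoring corrections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
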