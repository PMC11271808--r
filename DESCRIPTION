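Package: numaniso
Title: Radial-Tangential Anisotropy Displays and Inference for Numerosity
    Estimation
Version: 0.1.0
Authors@R:
    person("Numaniso", "Developers", email = "numaniso@example.org",
           role = c("aut", "cre"))
Description: Constructs peripheral-vision numerosity displays in which discs
    are arranged predominantly radially or tangentially around fixation using
    eccentricity-scaled elliptical interference zones, computes and matches
    the display properties that covary with numerosity (mean eccentricity,
    mean spacing, convex hull, occupancy area, density), simulates synthetic
    observers with participant-level random effects and central-tendency
    bias, and runs the full inference chain: participant screening,
    deviation scores, contrast-coded linear mixed models, likelihood-ratio
    interaction tests, cross-experiment comparisons, and simulation-based
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
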