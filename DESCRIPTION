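Package: fuzzcomfa
Title: Fuzzy Comprehensive Evaluation Driven CoMFA-Style 3D-QSAR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-endpoint 3D-QSAR toolkit for adverse-drug-reaction
    profiling of congeneric drug series.  Collapses per-endpoint scores
    (e.g. docking scores against toxicity-related protein targets) into a
    single comprehensive evaluation index (CEI) by fuzzy min-max membership
    and weighted aggregation; computes CoMFA-style steric (Lennard-Jones)
    and electrostatic (distance-dependent dielectric Coulomb) probe fields
    on a shared lattice for aligned molecules; fits partial least squares
    models with the full validation-statistic suite (leave-one-out q2,
    SEE, F, SEP, external Q2, progressive y-scrambling, field
    contributions); renders stdev*coeff contour grids; enumerates
    substituent derivatives of a template molecule; and provides the
    downstream screening-cascade, single-factor validation, reaction
    thermochemistry and exposure/risk arithmetic.
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
    ChemmineR,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
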