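Package: sasclip
Title: Clipping Trajectory Time Series that Match a Small-Angle Scattering Profile
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts, from a molecular-dynamics trajectory represented as a
    bead model, the longest contiguous time series whose ensemble-averaged
    small-angle X-ray scattering (SAXS) profile reproduces an experimental
    profile. Theoretical intensities are computed with the Debye equation
    using constant per-bead form factors; each candidate window's summed
    profile is fitted to the experimental curve with a scale factor and a
    constant offset, and accepted when the reduced chi-squared and, optionally,
    every low-angle squared residual fall below configurable thresholds.
    Clipped ensembles are characterized by domain-conformation descriptors
    (inter-domain angles, dihedrals and centre-of-mass distances), binned
    probability maps, a support-restricted Kullback-Leibler divergence against
    the source trajectory, the pair distance distribution p(r), isosbestic-point
    and linear-response analysis of per-frame curves, and convex recombination
    of clipped ensembles against a secondary observable. A seeded generator of
    hinge-motion multi-domain trajectories with planted target windows supports
    desk-scale validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    bio3d,
    generics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
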