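Package: twnscreen
Title: Topological Water Network Detection and Fragment Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects hydrogen-bonded four-membered cyclic water networks
    (topological water networks, TWNs) in explicit-water snapshots of a
    protein binding site, groups spatially recurrent networks into hot-spot
    clusters on a 3D grid followed by density-based refinement, and screens
    docked fragment poses against the grouped networks using a
    superposition-free Gaussian shape-density similarity together with the
    average orthogonal distance from the fragment centroid to the per-ring
    best-fit planes. Includes a seeded synthetic-data generator that plants
    water rings and fragment poses for end-to-end validation, plus a
    command-line front end for the gridbox/analysis/automation workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
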