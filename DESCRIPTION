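Package: conftor
Title: Conformational Vector Metrics for ABC Transporter Structures
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Standardized quantitative metrics for ABC Type I exporter
    structures. Defines conformational vectors ("conftors") between anchor
    points of annotated structural regions, computes inter-conftor angles
    and lengths, membrane tilt and insertion offsets, HELANAL-style helix
    bending geometry, helix-end projections onto the membrane plane, and a
    nearest-prototype classifier of transporter conformations
    (inward-facing, outward-facing, occluded). Includes Kabsch
    superposition and pairwise RMSD utilities, OPM-style membrane-model
    parsing, Poisson-Boltzmann membrane-grid configuration generation, and
    a synthetic-fixture generator producing toy transporters, ideal and
    kinked helices, and closing trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
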