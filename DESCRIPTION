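Package: fibrilmetrics
Title: Quantitative Analysis of Amyloid Fibril Mechanics, Helical
    Geometry, Sequence Amyloidogenicity and Internal Cavities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale quantitative toolkit for patient-derived amyloid
    fibrils, centred on immunoglobulin light-chain (AL) fibrils. Measures
    contour and end-to-end lengths of fibril traces and estimates the
    persistence length by least-squares fitting of the two-dimensional
    worm-like-chain relation, converting it to a bending rigidity.
    Relates helical rise and twist to pitch and cross-over distance,
    builds and analyses protofilament stacks, recovers screw symmetry
    from atomic models and maps inter-layer residue contacts. Computes
    Kyte-Doolittle hydropathy profiles, a 0-5 consensus amyloidogenicity
    score from five aggregation predictors, and germline-mutation lists
    with structural classification. Quantifies the native-versus-fibril
    conformational switch around the intramolecular disulfide bond, and
    detects sealed interior cavities on an occupancy grid with a
    flood-fill kernel. A synthetic-data module generates worm-like-chain
    trace ensembles, idealized protomer layers, cavity phantoms and
    germline/patient sequence pairs so every stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
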