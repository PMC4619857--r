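Package: scnsurf
Title: Seed-Based Structural Covariance Networks on Cortical Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Vertex-wise analysis of cortical-thickness structural covariance
    networks on triangulated surface meshes. Builds per-group seed-to-cortex
    covariance maps, group-difference and sleep-quality-modulation interaction
    fields, and applies random field theory familywise-error correction
    (residual-based smoothness estimation, resel counting, Euler-characteristic
    densities, peak and cluster-extent p-values). Includes a synthetic cohort
    and smooth-field thickness simulator so the whole pipeline is testable
    without imaging data, plus readers and writers for GIFTI surfaces, OBJ
    meshes and tab-separated statistic maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    Matrix,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
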