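Package: polycort
Title: Multiscale Association of Polygenic Scores with Cortical Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating a per-subject polygenic score to surface-based
    cortical morphometry in developing cohorts. Implements vertexwise general
    linear models with quadratic age terms and score-by-age interactions,
    random field theory cluster-level correction on triangulated surface
    meshes, spherical spin-permutation and reassignment null models for
    spatially autocorrelated brain maps, cell-type specificity-weighted and
    marker-gene expression scoring across cortical areas, cross-disorder
    effect-size map similarity with corrections for multiple comparisons, and
    age-group / age-centering analyses. A synthetic-data module generates
    icosphere meshes, cohorts, morphometry with planted effects, atlas label
    maps, expression panels and disorder maps so that every stage of the
    pipeline can be exercised and calibrated without access to restricted
    imaging, genotype or transcriptomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
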