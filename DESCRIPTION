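Package: fieldsteer
Title: Electric-Field Modeling and Current Steering for Multi-Electrode
    Transcranial Direct-Current Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finite-element modeling of transcranial direct-current
    stimulation (tDCS) electric fields in multi-tissue volume-conductor
    head models, with a cerebellar lobule-targeting workflow. Provides a
    synthetic multi-shell spherical head phantom with a wedge-parcellated
    pseudo-cerebellum and scalp electrode catalogs, a closed-form
    Legendre-series oracle for concentric-shell potentials, a first-order
    tetrahedral Laplace solver with Neumann current injection, atlas-based
    region-wise field extraction, lead-field (transfer-matrix) assembly
    over candidate electrodes, convex montage optimization under
    zero-net-current and total-current safety constraints, and an N-way
    ANOVA layer with eta-squared effect sizes and Bonferroni post-hoc
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    pracma,
    car,
    RNifti,
    jsonlite,
    yaml,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
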