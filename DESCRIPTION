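Package: anchorFS
Title: Multi-Modal Feature Selection with Anchor Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint feature selection across multiple data modalities
    (for example MRI-, PET- and CSF-derived biomarker blocks describing
    the same subjects) by l2,1-norm regularized least-squares regression
    with an anchor-graph Laplacian penalty and a simplex-constrained
    feature weight vector. Anchor graphs give a sparse row-stochastic
    sample-to-anchor affinity whose implied sample-sample similarity
    never needs to be materialized, the row-sparse weight matrices are
    obtained by iteratively reweighted closed-form updates, and the
    simplex weights are solved by an augmented Lagrangian method.
    Includes a seeded multi-modal data simulator with known informative
    support, feature-ranking utilities, and a stratified cross-validation
    harness with a linear support vector machine as downstream
    classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
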