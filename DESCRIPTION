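Package: cladospace
Title: Morphological Disparity and Phylogenetic Regression on Cladistic
    Character Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies morphospace evolution from discrete-character
    (cladistic) matrices: Maximum Observable Rescaled Distances (MORD),
    weighted mean pairwise dissimilarity, principal coordinates with
    Lingoes correction, post-ordination disparity metrics (sum of
    variances, sum of ranges, centroid displacements) with bootstrap and
    rarefaction confidence intervals, PERMANOVA between groups,
    distance-based phylogenetic generalized least squares with residual
    randomization, parsimony tree-length scoring and Fitch ancestral-state
    imputation, minimum-branch-length time calibration, and a synthetic
    data generator (birth-death trees, Mk characters with taxon-wise
    missing data, Brownian-motion body mass) so the whole workflow is
    testable without external files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    vegan,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
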