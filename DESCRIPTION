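Package: hccar
Title: Hierarchical Canonical Correlation Analysis for Multi-View Data
    Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates two or more sample-aligned high-dimensional views
    (e.g. transcriptome, methylome, per-gene mutation counts and
    environmental measurements) into a single joint representation by
    recursive, condition-number-guided canonical correlation analysis.
    Within-view covariances are regularized by reconditioning to a target
    condition number, optionally augmented with a normalized graph
    Laplacian so that interacting features receive similar projection
    weights. Includes pairwise and tensor CCA baselines, canonical factor
    loading association analysis, a repeated support-vector-regression
    evaluation harness for phenotype prediction, and a synthetic
    multi-view generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
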