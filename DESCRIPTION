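Package: wishplan
Title: Wish-List Driven Automated Multi-Criteria IMRT Planning on Synthetic
    Thorax Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for automated intensity-modulated radiotherapy
    (IMRT) treatment planning driven by a prioritized wish-list. Generates
    seeded voxelized thorax phantoms emulating locally advanced non-small cell
    lung cancer geometry, computes beamlet dose influence matrices by ray
    tracing, and optimizes fluence maps by two-round lexicographic
    epsilon-constraint minimization with hard constraints, Goal/Sufficient
    objective semantics and a logarithmic tumor control probability (LTCP)
    target objective. Includes greedy integrated beam-angle optimization over
    a laterality-dependent candidate arc, automated conversion of the fluence
    plan's dose-volume histograms into a point/line-objective template with a
    normal tissue objective, surrogate re-optimization of a deliverable-style
    plan, and plan-comparison machinery (DVH metrics, clinical constraint
    audits, population DVHs, bootstrap DVH-difference bands, exact Wilcoxon
    signed-rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    xml2,
    rhdf5,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nloptr,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
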