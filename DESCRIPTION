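Package: hemiasym
Title: Hemispheric Asymmetry Analysis of Weighted Structural Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds left and right hemispheric white-matter networks from
    whole-brain fiber-number and fractional-anisotropy connectivity
    matrices, computes weighted small-world graph metrics (clustering,
    characteristic path length, global/local/nodal efficiency) normalized
    against degree- and weight-matched random-network null ensembles,
    derives per-subject laterality (asymmetry) scores, and runs a
    group-by-hemisphere statistical battery with demographic covariates.
    Includes a synthetic connectome cohort generator with injectable
    hemispheric, group, nodal, and clinical effects so the whole pipeline
    is testable end to end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
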