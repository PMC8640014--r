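Package: trajatlas
Title: Progression Trajectories and Pseudotime for Multi-Study Transcriptome Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Harmonizes multi-study bulk RNA-seq cohorts into a frozen
    principal-component atlas, fits a start-anchored principal-curve
    progression trajectory with per-sample pseudotime, projects new bulk
    samples and single cells onto the frozen atlas via elastic-net drift
    correction, and tests genes, gene sets, somatic mutations, copy-number
    calls and survival for association with pseudotime.  Includes a
    negative-binomial synthetic-cohort generator emulating staged disease
    progression with dataset- and library-technology batch structure, and
    a reference-batch empirical-Bayes location/scale batch correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    survival,
    jsonlite,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    limma
Config/testthat/edition: 3
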