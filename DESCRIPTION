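Package: pcsig
Title: Principal-Component Gene Signatures for Confounded Overexpression Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attributes bulk transcriptome variation to an overexpressed gene
    in a two-cell-line, three-condition microarray design where the cell-line
    difference dominates total variance. Provides low-expression filtering,
    PCA by singular value decomposition with loading-threshold gene-signature
    selection (threshold W/sqrt(N)), hierarchical-clustering concordance for
    attributing components to experimental factors, a moderated t-test with
    empirical-Bayes variance shrinkage and Benjamini-Hochberg correction,
    hypergeometric over-representation analysis against GMT gene-set
    collections, and a seeded synthetic-data generator that emulates the
    design so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
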