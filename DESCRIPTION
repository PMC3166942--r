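Package: rowcollapse
Title: Collapsing Grouped Rows of Expression Matrices by Statistical and
    Network Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates the rows of a numeric matrix into one representative
    or composite row per group, as required when collapsing microarray probes
    to genes, genes to co-expression modules, or cell-type marker genes to
    abundance estimates. Implements representative selection by extreme row
    mean, mean absolute value, or row variance; hub selection by connectivity
    in a signed weighted correlation network; and composite summaries by
    column-wise average, first principal component (module eigengene), or a
    user-supplied function. Also provides a cross-dataset reproducibility
    framework based on Spearman correlations of ranked mean expression and
    ranked connectivity, marker-based cell-type deconvolution with
    fold-change marker selection, hypergeometric gene-list enrichment, and
    seeded simulators for probe-level, module-structured, and cell-mixture
    expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
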