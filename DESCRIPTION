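Package: sarcomix
Title: Clonality, Methylation Deconvolution and Molecular Classification
    for Multi-Component Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the integrated molecular analysis of tumors with
    histologically distinct components, motivated by pulmonary sarcomatoid
    carcinoma. Implements a clonality index with resampling-calibrated
    cutoffs to test common origin of paired microdissected components,
    leukocyte-fraction deconvolution of DNA methylation via a
    two-population mixture model, EMT scoring by signature principal
    component, single-sample gene set enrichment (ssGSEA) infiltration
    scores, Bayesian-regularized differential expression, methylation
    probe filtering and differential methylation calling, hierarchical
    molecular classification, nearest-centroid transcriptional subtype
    prediction, genomic summary statistics (mutation burden, shared
    mutation and copy-number fractions, two-leaf phylogenies, Monte Carlo
    mutual-exclusivity tests), and seeded synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    IRanges,
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
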