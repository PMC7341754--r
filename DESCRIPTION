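Package: hbmultiomics
Title: Multiomics Classification and Target Discovery for Hepatoblastoma-Like Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a hepatoblastoma multiomics
    analysis workflow: copy-number-aware somatic/germline variant filtering
    with predictive-value validation, two-step DNA-methylation consensus
    clustering (F versus E, then E1 versus E2), per-probe differential
    methylation with Fisher-exact region-set enrichment, negative-binomial
    likelihood-ratio differential expression with gene-set testing and
    variable-gene PCA, methylation-expression starburst integration
    including genotype-corrected NQO1 expression at rs1800566, and
    Kaplan-Meier/log-rank survival comparison of the discovered clusters.
    Ships a synthetic-cohort generator that emulates the study's data
    structure so every stage is testable end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    MASS,
    survival,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    optparse
Config/testthat/edition: 3
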