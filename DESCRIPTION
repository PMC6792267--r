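Package: svcis
Title: Integration of Somatic Structural Variant Breakpoints with Gene
    Expression and DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Breakpoint-proximity association scans linking somatic
    structural variant (SSV) breakpoints to nearby gene expression and
    CpG-island DNA methylation across cancer cohorts. Provides binary
    genomic-region-window and capped closest-breakpoint-distance predictor
    matrices, covariate-adjusted per-feature linear models with
    Storey-Tibshirani q-values and patient-shuffling permutation nulls,
    topologically-associated-domain (TAD) disruption and enhancer-hijacking
    annotation of rearrangements, comparison of normal-tissue methylation
    between rearranged regions and nearby CpG islands, per-sample
    structural-variation burden indices with global molecular correlates,
    and a synthetic multi-omic cohort simulator with a ground-truth ledger
    for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
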