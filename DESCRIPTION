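Package: methdiff
Title: Tissue-Differential DNA Methylation from Replicated Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls per-cytosine methylation from bisulfite-sequencing count
    tables with an explicit conversion-error model, infers conserved (CMS)
    and differentially methylated sites (DMS, Fisher's exact test) between
    two tissues, builds differentially methylated regions (DMRs) as runs of
    same-direction DMSs with a permutation-calibrated length threshold, and
    quantifies how reproducible these calls are across biological replicates
    (pairwise comparisons, false-positive rates relative to a
    combined-replicate reference, neighbor-joining clustering of methylomes).
    Regional methylation is summarised by context-specific read proportions
    (prop values) and coupled to differential gene expression via Spearman
    correlation with sequential Bonferroni correction, TSS methylation
    profiles, and a TE-distance linear model. A synthetic-data generator
    with planted truth makes the full pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
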