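Package: SexBiasTx
Title: Sex-Biased Transcriptome Analysis for Preimplantation Embryos
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An integrated, simulation-backed pipeline for dissecting sex
    differences in bulk embryo transcriptomes: PCR-amplicon embryo sexing and
    stage-wise sex-ratio statistics, TPM normalization and negative-binomial
    differential expression with fold-change/FDR thresholds, X-to-autosome
    dosage-compensation ratios with stratified bootstrap confidence intervals,
    percent-spliced-in (PSI) skipped-exon analysis with effective-length
    normalization, protein-domain to genomic coordinate lift-over and
    domain-disruption calls, and SQANTI-style long-read isoform classification
    with gene-set integration. A fully seeded synthetic-data generator
    produces annotation, sequences, counts, junction tables, domain hits and
    isoform chains with known ground truth so every stage is testable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
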