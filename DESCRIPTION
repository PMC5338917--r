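Package: regSNPscan
Title: Integrative Prioritization of Regulatory SNPs in Tissue-Specific
    Enhancers
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies candidate regulatory single-nucleotide polymorphisms
    (SNPs) that fall inside tissue-specific regulatory regions (open
    chromatin and active-enhancer intervals bound by master transcription
    factors), associate with nearby gene expression in a cis-eQTL one-way
    ANOVA scan, and change transcription-factor binding motifs in an
    allele-specific position-weight-matrix analysis. Candidate target genes
    are further annotated with tumor-versus-normal differential expression
    and with Kaplan-Meier / log-rank analysis of biochemical-recurrence-free
    survival after z-score stratification against normal samples. A fully
    seeded synthetic-data generator emulates the processed inputs (peak BED
    files, SNP manifest, genotype and expression matrices, reference
    sequence, HOMER-style motif models, clinical follow-up) with planted
    ground truth, so the entire pipeline is testable end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
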