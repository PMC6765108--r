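Package: kataegisBIR
Title: Mutation Clusters, APOBEC Signatures and Rearrangements from
    Break-Induced Replication
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to detect and characterize clustered hypermutation
    (kataegis) arising from APOBEC3A deamination of single-stranded DNA
    during break-induced replication (BIR) in yeast. Implements variant
    filtering with allele-fraction zygosity classification, cluster
    calling against a negative-binomial inter-mutation-distance null,
    pyrimidine-normalized substitution spectra with TC/TCW trinucleotide
    motif statistics, strand bias and strand coordination tests,
    fluctuation-style reversion-rate summaries with order-statistic
    confidence limits, copy-number step detection from windowed read
    depth, and a mechanistic simulator of ssDNA deamination,
    UNG1-dependent lesion processing and gross chromosomal
    rearrangement formation that generates truth-labelled synthetic
    cohorts for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
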