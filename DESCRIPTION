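Package: imprintr
Title: Detection of Parent-of-Origin Expression Bias in Reciprocal F1-Hybrid RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Allele-specific RNA-seq analysis for reciprocal F1-hybrid designs.
    Assigns uniquely mapping reads to parental alleles via strain-distinguishing
    SNPs, builds an in-silico alternate-strain pseudogenome, discovers unannotated
    transcription units by strand-matched read clustering, produces gene-by-sample
    allelic count matrices with CPM/RPKM normalisation, and tests each gene for
    allelic imbalance with a negative-binomial generalized linear model likelihood
    ratio test in each cross direction. Genes significant (Benjamini-Hochberg
    FDR <= 0.05) in both reciprocal crosses are classified as maternally or
    paternally imprinted or strain-biased according to the direction of the
    imbalance in each cross. A synthetic-data generator emulating a six-line
    reciprocal trophoblast stem cell experiment makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    SummarizedExperiment,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
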