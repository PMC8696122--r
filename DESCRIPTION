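Package: lncnet
Title: LncRNA Classification, Differential Expression and ceRNA Network
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for long noncoding RNA (lncRNA) analysis in bulk RNA-seq
    studies with a tissue-by-stage replicate design: filtering of candidate
    novel transcripts, a coding-potential consensus, positional classification
    of lncRNAs into five categories (intergenic, bidirectional, intronic,
    antisense, sense-overlapping), FPKM normalization and threshold-based
    differential expression calling, lncRNA target assignment by antisense,
    cis and trans mechanisms, competing endogenous RNA (ceRNA)
    mRNA-miRNA-lncRNA triplet inference with a hypergeometric shared-sponge
    test, over-representation analysis and gene set enrichment analysis with
    signal-to-noise ranking and phenotype-permutation normalized enrichment
    scores. A negative-binomial synthetic-data generator with planted ground
    truth (fold changes, positional categories, target pairs, ceRNA triplets)
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
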