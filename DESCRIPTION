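Package: melroot
Title: Transcriptomic and Phenotypic Analysis of Melatonin-Treated Rice Roots
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable implementation of the computational analysis used to
    characterise melatonin-induced changes in the rice root transcriptome:
    FPKM quantification from single-library counts, fold-change calling of
    differentially expressed genes and their co-regulated intersections,
    log2/z-score profile normalisation with K-means clustering and
    silhouette-based selection of the number of clusters, hypergeometric
    (one-sided Fisher) over-representation testing shared by GO-term and
    promoter cis-element enrichment, strand-aware promoter extraction with
    IUPAC-degenerate motif scanning, and the validation statistics
    (qRT-PCR delta-delta-Ct concordance, root gravitropism angle analysis).
    A synthetic-data generator emulates the three-library study design with
    recorded ground truth so every stage can be exercised and checked for
    recovery of planted structure.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    cluster,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
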