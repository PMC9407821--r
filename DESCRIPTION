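Package: convergeomics
Title: Convergent Cross-Species Transcriptomics and Promoter Methylomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting convergent gene-expression and promoter-methylation
    shifts between two focal species and a panel of outgroup species. Implements
    gene-length-corrected trimmed-mean-of-M-values (GeTMM) normalization of
    ortholog count matrices, negative-binomial exact tests with convergent
    differentially-expressed-gene calling, whole-genome bisulfite methylation
    quantification (CG/CHG/CHH contexts, binned and gene-element levels, metagene
    profiles), one-tailed Wilcoxon promoter differential-methylation calling,
    methylation-expression inverse integration, and hypergeometric
    over-representation analysis. Ships a synthetic-data generator with planted
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    ape,
    yaml,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
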