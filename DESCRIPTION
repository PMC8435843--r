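Package: wildcrop
Title: Comparative Diversity Analysis of Wild and Domesticated Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the genomic footprint of a domestication
    bottleneck from transcriptome data of a wild and a domesticated gene pool.
    Computes per-gene nucleotide diversity (pi, synonymous and nonsynonymous
    pi via Nei-Gojobori site counting), Tajima's D, the inbreeding coefficient
    F and Hudson's F_ST from coding-sequence genotype alignments; performs
    TMM-normalized negative-binomial exact tests for differential expression
    and per-pool expression-diversity (coefficient of variation) analysis;
    tests expression-diversity loss in selection candidates with a
    diversity-matched resampling null; and detects signed weighted
    co-expression modules with enrichment testing. A synthetic-data generator
    emulating a selfing crop/wild-relative design (bottleneck, selective
    sweeps, biased downregulation, planted co-expression modules) makes every
    stage testable without external data.
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
    jsonlite,
    yaml,
    edgeR,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
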