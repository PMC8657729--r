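Package: xsci
Title: Cross-Species Spinal Cord Injury Transcriptome Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing injury-induced transcriptional responses
    across species. Implements per-study empirical-Bayes moderated-t
    differential expression with Benjamini-Hochberg adjustment and
    probeset-to-gene collapsing, ortholog harmonization onto a reference
    organism (including chained mappings), classification of cross-species
    direction-of-expression concordance, hypergeometric gene-set
    over-representation with -log10 enrichment scores, amino-acid sequence
    conservation analysis (percent identity, Poisson-corrected distances,
    neighbor-joining trees), confidence-filtered protein-interaction
    networks, and immunostain area-fraction quantification with two-way
    ANOVA and Holm-Sidak comparisons. A synthetic-data generator with
    planted structure makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    car,
    dplyr,
    EBImage,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    limma,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
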