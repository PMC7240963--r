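Package: traitnet
Title: Significance-Filtered Trait Correlation Networks for Introgression-Line Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds class-annotated Spearman correlation networks from replicate-level
    trait measurements of a genotype panel, such as metabolite, lipid, volatile and
    phenotype profiles of a tomato introgression-line population. Replicate tables are
    aggregated to a standardized lines-by-traits matrix; all trait pairs (or trait by
    transcript pairs across two matrices) are tested with permutation-based Spearman
    p-values; edges surviving coefficient and significance cut-offs are assembled into
    networks that can be summarized per annotation-class pair, exported to GraphML, SIF
    or edge lists, and mined for candidate genes whose expression tracks metabolite
    levels. Includes genotype-group expression comparisons (fold change with
    significance stars) and a synthetic-population generator with known planted
    correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
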