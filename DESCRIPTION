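Package: encult
Title: Enrichment-Culture Community Analysis for Marine Sediment Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing why enrichment culturing recovers rare and
    dormant marine sediment bacteria. Implements isolate-to-amplicon
    recruitment by percent identity, the pseudocounted degree-of-enrichment
    ratio with enriched/not-enriched classification, the 16S rRNA to rRNA-gene
    activity ratio with active/dormant classification, rarefaction and
    alpha-diversity estimators (Chao1, ACE, Shannon, Simpson), OTU
    co-occurrence network inference with zero-occurrence and abundance
    filters, and a cofactor-pathway completeness screen that nominates
    syntrophic donor-recipient pairs. A synthetic enrichment-community
    generator with planted ground truth (r/K strategists, a dormant seed
    bank, paired DNA/RNA libraries, planted correlations) makes every stage
    testable without sequencing data.
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
    ggplot2,
    generics,
    readr,
    stringr,
    withr,
    jsonlite,
    yaml,
    vegan,
    igraph,
    Biostrings,
    Rcpp,
    stats,
    utils,
    methods,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
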