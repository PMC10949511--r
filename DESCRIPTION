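Package: ascomm
Title: Community Ecology of Activated-Sludge Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of activated-sludge 16S OTU tables from
    wastewater treatment plant surveys: table import, singleton removal and
    rarefaction; alpha diversity, Bray-Curtis dissimilarity and principal
    coordinates analysis; Sloan neutral community model fitting with bootstrap
    confidence intervals and per-taxon partitioning; consensus co-occurrence
    network inference combining Spearman screening with CLR
    neighborhood-selection lasso under StARS stability selection; functional
    guild (AOB, NOB, PAO, BFB, anammox) extraction and summaries;
    genome-sequenced proportion (microbial dark matter) accounting against
    reference 16S sets; redundancy analysis of operational parameters; and
    seeded synthetic-data generators exercising every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    ape,
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
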