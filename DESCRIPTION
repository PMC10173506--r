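Package: nichewebs
Title: Niche-Breadth Classification and Co-Occurrence Network Analysis for
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies amplicon sequence variants (ASVs) into habitat
    generalists, common taxa, and specialists from Levins' niche breadth,
    builds Spearman co-occurrence networks with false-discovery-rate edge
    filtering, normalizes network topology against Erdos-Renyi null models
    (small-world coefficient), assigns Guimera-Amaral node roles from
    within-module degree and among-module connectivity, and summarizes
    module distribution patterns along environmental gradients. Includes a
    synthetic elevation-gradient community generator with full ground truth
    so every stage of the pipeline can be validated end to end.
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
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
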