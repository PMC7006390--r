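Package: pathlevels
Title: Multi-Level Pathway Crosstalk Networks from Offline KEGG Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds n-level networks of interconnected biological pathways
    around user-chosen first-level pathways, using an offline snapshot of a
    KEGG-style pathway resource (KGML files or flat tab-separated tables).
    Candidate genes are highlighted inside the network and partitioned by
    why they fall outside it; differential-expression networks are colored
    by fold-change bins; over-representation of candidate genes per pathway
    is assessed with an upper-tail hypergeometric test against the global
    or network-restricted background. Includes a seeded synthetic fixture
    generator with planted ground truth, deterministic interactive HTML
    network export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
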