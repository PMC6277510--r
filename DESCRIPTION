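Package: trucphylo
Title: Structural Phylogenomics and Mosaicism Diagnostics for the Fourth
    Branch of Microbes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether giant viruses (Megavirales) form a
    fourth branch of microbes alongside Archaea, Bacteria and Eukarya.
    Implements binary presence/absence structural phylogenomics from
    protein fold-superfamily assignment tables: maximum parsimony tree
    search with Fitch counting, bootstrap split support, Lundberg
    a-posteriori rooting, and per-character consistency, retention,
    homoplasy and Goloboff fit indices against character age; age-weighted
    (1-nd) principal coordinate ordination of proteomes; Pearson-distance
    hierarchical clustering of informational-gene phyletic profiles;
    four-genome pangenome partitioning at ProteinOrtho-style homology
    thresholds; and genome and gene "rhizome" mosaicism classification
    from taxonomy-annotated best hits, including 40-amino-acid sliding
    window fragment rhizomes. A synthetic-data module generates character
    matrices on a known four-group tree, genomes with planted gene
    families, and truth-labeled hit tables so the whole evidence chain is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
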