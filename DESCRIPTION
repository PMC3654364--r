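Package: consnet
Title: Cross-Species Alignment of Protein Interaction Networks via
    Homolog-Group Alignment Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Global alignment of pairwise and three-way protein-protein
    interaction (PPI) networks. Cross-species alignment-graph nodes are
    formed from precompiled homolog (KO-style ortholog) groups; edges mark
    interactions conserved across the aligned species; conserved modules
    are the connected components of that graph, found with an explicit-stack
    Tarjan traversal. Each module is scored for sequence-similarity
    confidence, interaction conservation (cliqueness), and GO
    biological-process coherence, combined into a normalized [0,1] score
    with empirical resampling p-values, and optionally refined by iterative
    connected-components finding (ICCF). Evaluation utilities compute
    KO-based specificity and sensitivity, GO process-coherence metrics via
    a hypergeometric enrichment test with false-discovery-rate correction,
    and MIPS complex/FunCat coverage. A fully seeded synthetic-benchmark
    generator with planted conserved modules and ground truth makes the
    whole pipeline testable without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
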