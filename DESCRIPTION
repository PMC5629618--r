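Package: moanet
Title: Network-Based Drug Repositioning from Signaling-Network Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-specific disease signaling networks (Pnet) and
    per-instance drug mechanism-of-action networks (MoAnet) by shortest-path
    linking of source genes, activated transcription factors and up-regulated
    target genes over a protein-protein interactome, scores drugs by the node
    overlap between their MoAnets and the patient Pnet, and evaluates top-k
    enrichment of screening-active drugs in the resulting ranking. Includes
    strict readers and writers for the tabular and graph formats involved, a
    deterministic synthetic-fixture generator with planted ground truth, and
    ggplot2 visualisations of the enrichment results.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
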