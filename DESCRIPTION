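Package: pserm
Title: Position-Specific Enrichment Ratio Matrix Analysis of Directed-Evolution Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes deep-sequencing data from directed-evolution campaigns
    (e.g. yeast-display antibody affinity maturation). Turns merged amplicon
    reads into per-round, per-replicate tallies of mutation strings, builds
    position probability matrices with square-root pseudocounts, derives
    position-specific scoring matrices (PSSMs) against a uniform background
    and position-specific enrichment ratio matrices (PSERMs) as
    consecutive-round PSSM differences, scores and ranks clones under these
    matrices alongside conventional frequency and enrichment-ratio metrics,
    and applies developability filters (unpaired cysteines, CDR net charge).
    A synthetic sorting-campaign generator with ground-truth fitness makes the
    whole pipeline testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
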