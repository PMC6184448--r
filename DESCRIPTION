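Package: amcoreset
Title: Comparative Transcriptomics of Arbuscular Mycorrhizal Symbiosis Core Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for identifying a conserved core set of
    arbuscular-mycorrhizal-symbiosis (AMS) genes by comparative
    transcriptomics. Provides read-level quality filtering, RPKM
    quantification, an empirical-noise (NOISeq-style) differential
    expression caller, orthogroup-based cross-species conservation
    scoring with Venn partitions and core-set extraction, curated-gene
    cross-referencing, promoter cis-element scanning with mismatches,
    Trouvelot mycorrhizal colonization scoring, qPCR relative
    quantification, seed-deterministic synthetic-data generators with
    planted ground truth, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
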