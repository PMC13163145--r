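Package: orthostress
Title: Comparative Cold-Stress Transcriptomics Across Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative analysis of cold-stress transcriptomes
    across species: phylostratigraphic gene-age assignment from orthogroup
    presence/absence on a rooted species tree, negative-binomial differential
    expression with DEG/HDEG classification, orthogroup-level cross-species
    sharing analysis, co-expression module detection with hypergeometric
    enrichment and hub-gene ranking, and a gene-age by transcriptional-
    plasticity trend test. Includes a fully specified synthetic-data
    generator with planted truth so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
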