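Package: cordhox
Title: Spinal-Cord Homeobox Gene Expression, Interactome Crossing and
    Regulatory-Network Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for identifying genes overexpressed in one
    central-nervous-system region relative to others from median-expression
    tables, confirming them by Welch differential expression with Bonferroni
    correction, crossing their first-shell protein interactors with a human
    transcription-factor catalog, quantifying overlap with a co-expression
    module by an exact hypergeometric over-representation statistic, screening
    Gene Ontology term co-occurrence for pathway antagonism, and assembling the
    evidence into a typed regulatory network. Ships seeded synthetic-data
    generators emulating every input class so all stages are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, NetworkInference, GeneSetEnrichment, GO,
    Transcriptomics
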