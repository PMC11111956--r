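Package: tripletag
Title: Joint Entity and Relation Extraction by Token-Pair Global Matrix
    Tagging, with Knowledge-Graph Question Answering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: One-step joint extraction of typed entities and relational
    triples from character-tokenized clinical text. Sentences are scored as
    three families of token-pair matrices (entity head-tail, subject-head to
    object-head, subject-tail to object-tail) produced by a biaffine scorer
    over a common-sequence self-attention encoder and fused with a rotary
    position global pointer head, trained with a multi-label cross-entropy
    loss over matrix cells. Includes a schema-driven synthetic corpus
    generator for venous thromboembolism style annotations, triple-level
    evaluation metrics, knowledge-graph aggregation with CSV export in graph
    database bulk-import layout, and rule-based template question answering
    over the extracted graph.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
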