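Package: medkg
Title: Quintuple-Based Medication Knowledge Graphs with Ontology
    Validation and Graph Reasoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Build, validate and reason over clinical medication knowledge
    graphs assembled from (subject, subject-type, relation, object,
    object-type) quintuples. Provides a labeled property graph with
    frequency-weighted relations stored as doubly linked edge records, an
    ontology schema layer (medication types, their attribute ontologies,
    a relation vocabulary and category-pair constraints), dictionary-
    assisted term standardization and longest-match segmentation, six
    graph-reasoning procedures (multi-hop indication discovery, weighted
    critical-path synergy mining, minimum-spanning-tree extraction of
    core dosing knowledge, symptom-intersection maps, comorbidity
    shortest paths and stage-aware topological retrieval), a seeded
    synthetic-graph generator with planted recoverable patterns, and
    readers/writers for quintuple tables, graph JSON, GraphML and
    openCypher scripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    xml2
VignetteBuilder: knitr
Config/testthat/edition: 3
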