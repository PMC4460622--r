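Package: hoilattice
Title: Health Outcome of Interest Definition via Semantic Query Expansion
    and Formal Concept Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic definition of Health Outcomes of Interest
    (HOIs) from free-text queries over a repository of merged biomedical
    ontologies. A query is tokenized and matched lexically against every
    concept synonym, expanded along the subsumption hierarchy by two
    rounds of sub-concept derivation ("2-hop") and a minimal ancestor
    cover, and refined by Formal Concept Analysis: a concept lattice is
    built over the matched and derived concepts with their
    super-concepts as attributes, traversed top-down, and pruned by a
    sub-concept coverage ratio with optional user (or gold-standard)
    feedback that eliminates subsumed concepts. Includes OBO and TSV
    ontology loaders with cross-ontology xref merging and cycle
    detection, a NextClosure lattice enumerator, deterministic synthetic
    ontology and context generators for end-to-end testing, a
    sensitivity/specificity evaluation harness, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
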