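Package: litexpand
Title: Concept-Based Query Expansion and Weighted Retrieval for Gene Lists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene-list-driven literature retrieval. Each input gene is
    expanded, through an organism-scoped concept thesaurus, into four
    concept classes (gene names and symbols, protein names, pathway names,
    disease names). Documents (title plus abstract) are scored per class
    over an inverted index with a classic TF-IDF similarity, and the four
    per-class scores are fused into a final ranking by user-settable class
    weights that can be changed instantly without re-running retrieval.
    Includes a TREC-style evaluation harness (average precision, MAP,
    precision at k) and a synthetic fixture generator with planted term
    occurrences for end-to-end testing without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
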