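Package: syndromeKG
Title: Knowledge-Graph-Augmented Multilabel Syndrome Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for knowledge-graph-assisted diagnosis of traditional
    Chinese medicine (TCM) syndromes from electronic medical records.
    Syndrome differentiation is cast as multilabel ranking over
    disease-nature and disease-location labels. The package builds a
    four-relation medical knowledge graph from structured records, trains
    translational and bilinear knowledge-graph embeddings (TransE,
    DistMult, ComplEx) with margin ranking loss, fuses entity embeddings
    into a character-level transformer text representation, and evaluates
    predictions with precision-at-k, Hamming loss, average precision and
    label ranking loss, plus link-prediction metrics (MRR, MR, Hits@N).
    A synthetic-record generator with planted syndrome and label structure
    makes every stage testable without access to clinical data.
License: MIT + file LICENSE
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
RoxygenNote: 7.3.3
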