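Package: sdprel
Title: Clinical Relation Extraction with Sentence and Shortest Dependency Path Encoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies relations between clinical entity mentions (problems,
    treatments, tests) in sentence context using a dual-branch recurrent neural
    network: a bidirectional LSTM over the entity-masked token sequence with
    word and relative-position embeddings, and a second branch that encodes the
    shortest dependency path between the two target entities via a pairwise
    convolution over neighboring path words fused with dependency-relation-type
    embeddings. Includes readers for i2b2-2010-style annotation files, CoNLL-U
    dependency parses and word2vec text embeddings, a synthetic-corpus
    generator with controllable syntactic signal, mini-batch training with
    Adam, micro-averaged evaluation with document-level cross-validation, and
    a command-line pipeline.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
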