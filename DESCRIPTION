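Package: clinevent
Title: Clinical Event Detection with Relative-Position Attention, CRF
    Decoding and Label-Preserving Data Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for detecting clinical events (problems, tests,
    treatments, evidentials, occurrences, clinical departments) in
    pre-tokenized narrative text, framed as BIOES sequence labeling.
    Character-level and word-level features are fused and encoded by a
    direction-aware relative-position multi-head self-attention stack with
    un-scaled attention, and decoded by a linear-chain conditional random
    field with Viterbi search. Includes a label-preserving lexical data
    augmentation engine that substitutes non-event words by priority-ordered
    lexicon relations (synonyms, antonyms, hypernyms, hyponyms, related
    words); strict, lenient-span and type-accuracy evaluation; a synthetic
    corpus generator for end-to-end testing; and a command-line interface
    covering the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
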