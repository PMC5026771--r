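Package: bioevent
Title: Biological Event Extraction with Annotation-Adjusting Informed EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts biological events (nine GENIA event types with THEME and
    CAUSE arguments) from sentences annotated in BioNLP'09-style standoff
    format. Sentences are encoded as labeled directed graphs over anchor
    words; a multi-label linear structured model scores node and edge label
    assignments and is trained either by a cost-sensitive Passive-Aggressive
    baseline or by an Informed EM algorithm that adjusts gold-standard
    trigger annotations under posterior constraints (basic, confidence,
    non-overlapping and distance constraints) to reduce trigger-span
    inconsistency. Includes trigger-lexicon construction with reliability
    scoring, dependency-path feature extraction, exact per-sentence decoding
    with refinement, event-level evaluation, and a synthetic corpus
    generator with controllable trigger-span inconsistency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
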