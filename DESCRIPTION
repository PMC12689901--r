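Package: clinspan
Title: Span Annotation, Evaluation, and Affirmed-Symptom Extraction for
    Clinical Free Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning span-annotated clinical free text (short,
    German-style emergency-department anamnesis narratives) into structured
    records of affirmed symptoms, and for evaluating any named-entity
    recognition backend against gold annotations. Reads and writes
    Doccano-style JSONL with character-offset spans, converts between spans
    and token-level IOB tag sequences, scores predictions at four matching
    granularities (strict, exact boundaries, partial overlap, entity type)
    with MUC/SemEval-style correct/incorrect/partial/missing/spurious
    counts, measures inter-annotator agreement as entity-level F1, and
    post-processes predicted spans via confidence filtering, negation-cue
    scoping, anatomy-pain fusion, surface standardization, and dictionary
    normalization. A seed-deterministic synthetic corpus generator with a
    controlled corruption model and closed-form expected metrics makes
    every component testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
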