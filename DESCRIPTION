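Package: clinhist
Title: Age- and Temporally-Specified Clinical Events from Note Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents, extracts, normalizes, evaluates, and summarizes age-
    and temporally-specified clinical events from the history sections of
    clinical notes (discharge summaries, history and physical notes). Implements
    an expanded annotation schema with six named-entity classes (AGE, TIMEX3,
    SUBJECT_CLASS, DISEASE_DISORDER, PROCEDURE, OTHER_EVENTS), class-specific
    attribute vocabularies (including degree of biological relation and
    DocTimeRel), and typed relationships between entities; a JSON standoff
    reader and writer; a keyword section tagger; a rule-based recognizer for
    ages, temporal expressions, and subjects; an approximate dictionary matcher
    for disorders and procedures with semantic-type routing; attribute
    normalizers (age ranges, birth-time ranges, kinship degree); overlapping-
    span NER scoring with three-level inter-annotator agreement; descriptive
    corpus statistics; and a seeded generator of fictitious annotated notes for
    testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
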