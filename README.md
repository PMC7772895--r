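# clinhist

Age- and temporally-specified clinical events from the history sections
of clinical notes.

The past medical, past surgical, family, and social history sections of
discharge summaries and H&P notes carry the events that matter for risk
assessment and longitudinal research — "Father died of MI at age 69",
"s/p appendectomy 2001", "Ex-smoker, quit 10 years ago" — but almost
none of it reaches coded form. `clinhist` is an R implementation of an
expanded annotation schema and prototype extraction pipeline for these
events, for clinical NLP researchers and informaticists who need to
represent, extract, normalize, score, and summarize them.

## What it implements

* **Schema**: six named-entity classes — `AGE` (A), `TIMEX3` (T),
  `SUBJECT_CLASS` (S), `DISEASE_DISORDER` (DD), `PROCEDURE` (P),
  `OTHER_EVENTS` (OE) — with closed attribute vocabularies (age
  specificity, TIMEX3 type, subject normalization and *degree of
  biological relation* `-log2(relatedness)`: 0 identical twin, 1
  parent/sibling/offspring, 2 aunt/uncle/grandparent, 3 first cousin;
  `DocTimeRel` relating events to the document creation time; social-
  determinant types), concept codes, and typed relationships
  (`DD-to-S`, `OE-to-A`, ...). `validate_document()` enforces all of it.
* **Standoff I/O**: a deterministic JSON standoff dialect
  (`read_annotations()` / `write_annotations()`), plain-text notes with
  an optional `DATE:` header, and TSV concept lexicons (a demo lexicon
  with CUI-like codes ships in `inst/extdata/`).
* **Extraction**: a keyword section tagger; a rule-based recognizer for
  ages ("61-year-old", "age 69", "70s", "childhood"), temporal
  expressions (calendar dates, bare years 1900–2099, relative phrases,
  durations), and subjects (kin terms, implicit "family" mentions); and
  an approximate dictionary matcher for disorders/procedures using
  character-trigram Jaccard similarity with semantic-type routing
  (T047/T048/T046/T191 → DD, T062 → P).
* **Normalization**: age ranges ("70s" → [70, 79]) and birth-era time
  ranges ([70, 79] at reference 2029-10-10 → [1950-10-10, 1959-10-10]),
  kinship degree ("maternal uncle" → 2), TIMEX3 typing, DocTimeRel
  defaults.
* **Evaluation**: overlapping-span precision / recall / F1
  (`F1 = 2PR/(P+R)`) at three strictness levels — spans, + attributes,
  + relationships — and per-annotator agreement reports.
* **Corpus statistics**: entity-class distributions with per-document
  means, social-determinant distributions, and per-section history
  summaries (age/date specification, family-history degree and cancer
  site, smoking status).
* **Synthetic corpus generator**: seeded, fictitious discharge-summary
  style notes with gold offsets, attributes, and relationships,
  targeting the reference corpus marginals — the test harness standing
  in for access-restricted clinical corpora.

## Worked example

```r
library(clinhist)

note <- paste0("Past Medical History:\nCAD diagnosed in 1997.\n",
               "Family History:\nFather died of MI at age 69.\n",
               "Social History:\nEx-smoker.\n")
doc <- annotate_document(new_document("example", note,
                                      creation_date = as.Date("2014-03-01")))
doc$entities[, c("id", "class", "start", "end", "text")]
#>   id            class start end   text
#> 1 E1           TIMEX3    39  43   1997
#> 2 E2    SUBJECT_CLASS    45  51 Family
#> 3 E3    SUBJECT_CLASS    61  67 Father
#> 4 E4              AGE    82  88 age 69
#> 5 E5 DISEASE_DISORDER    22  25    CAD
#> 6 E6 DISEASE_DISORDER    76  78     MI
```

The pipeline found the year (a date-type `TIMEX3`), the explicit subject
"Father" (and the implicit "Family" of the section header), the age
span with the preposition excluded, and both disorders via the demo
lexicon's acronym synonym rows (`CAD` → C0010054, `MI` → C0027051), each
with a defaulted `DocTimeRel`. Normalizing the age against the document
creation date:

```r
age <- doc$entities[doc$entities$class == "AGE", ]
(rng <- normalize_age(age))
#> $start_age
#> [1] 69
#> $end_age
#> [1] 69
age_to_time_range(rng, doc$creation_date)
#> $start_date
#> [1] "1945-03-01"
#> $end_date
#> [1] "1945-03-01"
degree_relation("father")
#> [1] "1"
```

So the father's MI occurred around 1945 and he is a first-degree
relative. Scoring system output against gold annotations (here the gold
standard is the same document, so every class scores 1):

```r
gold <- doc
evaluate_ner(gold, doc, level = 1)
#> <clinhist_eval> level 1 (overlapping spans)
#>             class tp fp fn precision recall    f1
#>               AGE  1  0  0     1.000  1.000 1.000
#>  DISEASE_DISORDER  2  0  0     1.000  1.000 1.000
#>     SUBJECT_CLASS  2  0  0     1.000  1.000 1.000
#>            TIMEX3  1  0  0     1.000  1.000 1.000
#>           overall  6  0  0     1.000  1.000 1.000
```

A command-line wrapper over the same functions lives in
`inst/cli/clinhist.R` (`synth`, `sections`, `ner`, `eval`, `stats`
subcommands). See the vignette in `vignettes/` for the model,
conventions, and design decisions.

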