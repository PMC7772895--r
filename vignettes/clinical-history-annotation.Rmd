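---
title: "Annotating and extracting age- and temporally-specified events from clinical histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and extracting age- and temporally-specified events from clinical histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinhist)
```

## The problem

The history sections of discharge summaries and H&P notes — past medical
history, past surgical history, family history, social history — record
when things happened and to whom: "Father died of MI at age 69",
"s/p appendectomy 2001", "Ex-smoker, quit 10 years ago". This information
drives familial risk assessment (degree of relation, age of onset),
longitudinal phenotyping, and exposure analysis, yet it is rarely
available in coded form. `clinhist` implements an expanded annotation
schema for these events, a prototype recognizer for them, and the
evaluation and summary machinery needed to study both.

## The schema

Six named-entity classes cover a history mention and its anchors:

* `TIMEX3` (tag `T`) — TimeML-style temporal expressions, with a `type`
  of `date`, `time`, or `duration`.
* `AGE` (`A`) — age expressions, typed `fully-specified` ("age 69"),
  `less-specified` ("70s"), or `event-specified` ("childhood").
* `SUBJECT_CLASS` (`S`) — any subject who is not the patient, including
  implicit mentions (the "family" of a family-history header). Attributes:
  `normalization` (family_member / donor_other / donor_family_member /
  other), `implicit`, and `degree_relation` — the degree of biological
  relation, $-\log_2$ of the coefficient of relatedness: 0 for an
  identical twin, 1 for parents, siblings, and offspring (relatedness
  1/2), 2 for grandparents, aunts/uncles, half-siblings (1/4), 3 for
  first cousins (1/8), plus `not_biologically_related` and `unknown`.
* `DISEASE_DISORDER` (`DD`) and `PROCEDURE` (`P`) — terminology-mappable
  disorder and procedure mentions, carrying an optional concept code
  (`associated_code`) and `DocTimeRel`, the temporal relation of the
  event to the document creation time (`after`, `overlap`,
  `before_overlap`, `before`, `unknown`).
* `OTHER_EVENTS` (`OE`) — social determinants of health and other
  clinically relevant events, typed `martial status` (the canonical token
  as published; `marital status` is accepted as an input alias), `death`,
  `good health`, `substance use`, `occupation`, `exposure`,
  `living situation`, `outcome of procedures`, `other`; substance-use
  mentions may carry a concept code, and a `negated` input flag supports
  "never smoker" style assertions.

Typed, directed relationships (`DD-to-S`, `OE-to-A`, `P-to-T`, ...) link
an event to its subject, age, and time. The full legal pair set is
inferred from the schema's worked example and entity semantics, since no
exhaustive enumeration was published; `validate_document()` enforces it,
along with offset fidelity, attribute vocabularies, and the
`associated_code` restriction. Offsets are 0-based half-open — a
convention choice (span length is `end - start`) matching common standoff
practice. All attribute values are stored as strings so documents
round-trip bit-exactly through the JSON standoff format, which is this
package's native interchange (the annotation tool format used in the
original study is tool-specific and undocumented).

## Section tagging

`tag_sections()` matches header keywords case-insensitively at line
starts, optionally followed by a colon; each body runs to the next
recognized header. Only two header keywords were published as examples;
the shipped table adds the conventional clinical variants
("past surgical history", "surgical history", "PSH", ...) with two
guards: abbreviations match only as whole lines, and longer phrases win
over their substrings ("past surgical history" before "medical history").
Section ends were not described in the original corpus construction;
next-recognized-header is assumed. Text before the first header forms an
`other` section that downstream extraction never touches.

## Rule-based recognition (AGE, TIMEX3, SUBJECT_CLASS)

The published pattern inventory is limited to examples ("##-year-old",
"## yo", "YYYY-MM-DD"), so `rule_patterns()` is deliberately a documented
superset reconstruction. Choices that matter:

* AGE spans include the age word but not the preposition: "at age 69"
  yields "age 69", matching the published bracketing.
* Decade tokens ("70s") need a possessive, "age(d)", or kin-term context,
  so the "70s" of "1970s" or a plural noun never fires. Life-stage words
  (childhood, infancy, adolescence, teens) are `event-specified`.
* Bare years match only 1900–2099; medication quantities, room numbers,
  and pack-year exposure quantities — named false-positive modes for
  naive numeric patterns — are excluded by construction and exercised by
  the generator's distractor lines.
* Same-class overlaps resolve longest-match-first, then leftmost
  (maximal munch), deterministically and independent of rule order.

Subjects come from a term lexicon with `maternal`/`paternal` modifiers
kept in the span but stripped for degree lookup. In family-history
sections the "family" token of the header is emitted as an implicit
subject of unknown degree.

## Dictionary matching (DISEASE_DISORDER, PROCEDURE)

The medical classes are matched against a pluggable concept lexicon by
approximate string similarity, standing in for a licensed-terminology
matcher. Candidate spans are token windows of up to 6 tokens that neither
start nor end on a stopword and never cross a line break (history lists
are line-structured; this also prevents a window from swallowing two
adjacent list items). Similarity is the Jaccard coefficient over
character trigrams of normalized strings (lowercase, punctuation stripped
except intra-token hyphens, whitespace collapsed); the similarity metric
and threshold of the original system were not reported, so both are
explicit, tunable assumptions here (default threshold 0.8; at 1.0 the
matcher provably reduces to exact normalized dictionary lookup, which the
tests check against a naive substring-scan oracle). Strings under five
normalized characters match exactly only: trigram similarity is
meaningless for short forms, so acronyms (CAD, MI, CABG) resolve solely
through explicit synonym rows of the lexicon, and general abbreviation
disambiguation is out of scope.

Matches route to an entity class by semantic type: T047/T048/T046/T191
to `DISEASE_DISORDER`, T062 to `PROCEDURE`. T060 (diagnostic procedures)
is excluded by default — including it buys recall at a large precision
cost — but a custom map can add it. Overlapping matches resolve by
longest span, then highest similarity, then leftmost. A ~70-entry demo
lexicon with CUI-like codes ships with the package; it is a synthetic
stand-in sufficient for the examples and fixtures, not a terminology.

## Normalizers

* `normalize_age()`: "age 69" → [69, 69]; "70s" → [70, 79]; life stages
  via a configurable table (childhood [0, 12], infancy [0, 1],
  adolescence/teens [13, 19]). The numeric life-stage bounds are package
  conventions — the schema defines the category but no numeric map.
* `age_to_time_range()`: range [a, b] at reference date $r$ maps to
  $[r - b\,\mathrm{yr},\; r - a\,\mathrm{yr}]$, reproducing the schema's
  paired example ([70, 79] → [10/10/1950, 10/10/1959]); the reference
  date is the document creation date, and Feb 29 minus $n$ years lands on
  Feb 28 in non-leap years.
* `default_doctimerel()`: majority defaults per class — disorders
  `before_overlap` (chronic conditions dominate), procedures `before`
  (histories record completed interventions), other events
  `before_overlap`. All defaults live in one table; custom tables may add
  section-specific rows.

## Evaluation

`match_entities()` pairs gold and system entities one-to-one when spans
share at least one character and classes agree (no overlap proportion was
specified, so one character is the threshold), greedily by decreasing
overlap then gold offset. Three strictness levels: (1) span + class;
(2) plus equal attributes and concept code; (3) plus exact correspondence
of each matched entity's relationships under the pairing, with no partial
credit. Pairing is always computed at level 1 and stricter criteria
demote failing pairs to FP + FN — this makes the level nesting
F1(3) ≤ F1(2) ≤ F1(1) hold by construction and matches the observed
failure mode where two annotations agree on a span but differ on the
concept code. Precision, recall, and F1 use the 0-denominator → 0
convention. `iaa_report()` applies the same machinery per annotator
against a reference standard.

## Corpus statistics

`class_distribution()`, `sdoh_distribution()`, and `history_summary()`
reproduce conventional table arithmetic: percentages round half-up to
integers and per-document means half-up to 2 decimals (688/1540 → 45%,
140/110 → 1.27 — banker's rounding would not reproduce the printed
values). A mention counts as "age or date specified" when linked by a
relationship to an `AGE` or date-type `TIMEX3` entity, or — for corpora
annotated without relationships, as chart review tables typically are —
when one co-occurs on the same text line. Smoking status partitions
substance-use mentions by the negation flag (`never`) and DocTimeRel
(`before` = former, `before_overlap` = current). Two published
per-document averages (0.71 subjects/doc, 1.43 procedures/doc) do not
reconcile with the corresponding table counts over 110 documents and are
treated as computed on a different denominator; they are not reproduced.

## The synthetic corpus generator

Real clinical corpora in this space are access-restricted, so
`generate_corpus()` is a first-class module: it produces fictitious,
Safe-Harbor-style notes with gold standoff annotations, and it defines
the package's study conditions. Defaults encode the reference corpus
conditions: per-class mean mentions per document (TIMEX3 1.27, AGE 1.08,
SUBJECT_CLASS 0.67, DISEASE_DISORDER 6.25, PROCEDURE 1.46, OTHER_EVENTS
3.25 — the disorder rate is derived from the published totals over 110
documents, not a stated parameter), the social-determinant type mixture
from the published counts, and a 94% fully-specified age-type mixture.
Per-document counts are drawn as `floor(rate) + Bernoulli(frac(rate))`
rather than Poisson: corpus totals then concentrate tightly around the
configured rates (Bernoulli variance at most 1/4 per document) while
per-document counts still vary. Templates use only pattern-covered
surface forms and demo-lexicon terms, every planted slot is recorded with
exact offsets and attributes, canonical relationships are planted per
template, and distractor lines (medication doses, pack-years) exercise
the numeric false-positive modes. Generation is byte-deterministic under
the seed.

What the generator does *not* emulate — and therefore what passing tests
do and do not show: real notes have misspellings, unseen abbreviations,
free word order, section headers outside the keyword table, and concept
mentions absent from any lexicon. Self-consistency of the pipeline on
generated corpora (level-1 F1 ≥ 0.95 per class; in practice 1.0)
validates offsets, scoping, resolution order, and scoring machinery; it
is not an estimate of real-world recall, which for the original prototype
was moderate. The recognizer extracts five classes; `OTHER_EVENTS` is
represented, annotated, and summarized but never predicted (as in the
original system), so self-consistency is evaluated over the five
extracted classes.

`split_corpus()` apportions development/train/test/holdout sets by
largest remainder under the canonical 15:45:20:20 ratios; the original
study's realized split does not match any standard rounding of those
ratios, so the generator documents its own rule and does not claim to
reproduce that assignment.

## Problem sizes and numerical choices

The shipped tests run the full pipeline on a 110-document generated
corpus (matching the reference corpus size, ~1 150 entities, a few
seconds), statistical rate checks at n = 110 (3 standard errors) and
n = 1000 (5% relative tolerance, law of large numbers), and exhaustive
matching oracles on ≤ 6-entity fixtures. Percent/mean rounding uses a
1e-9 guard against binary representation of exact halves. Degenerate
inputs: empty text yields zero sections; a note without history sections
annotates to zero entities; `P = R = F1 = 0` when denominators vanish;
an absent creation date makes time-range normalization an error rather
than a guess.

## Known limitations

Pattern coverage is a reconstruction, not the original inventory; the
demo lexicon is synthetic and tiny; negation is accepted as input, never
detected; DocTimeRel is defaulted, never predicted from tense; the
section tagger is keyword-based by design (terminology- and
embedding-based tagging is explicitly future work); and chance-corrected
agreement (kappa) is out of scope alongside the original annotation
tool's undocumented internal agreement algorithm.
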