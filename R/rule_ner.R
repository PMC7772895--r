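# Rule-based recognizer for the non-medical classes: AGE, TIMEX3,
# SUBJECT_CLASS. Patterns are a documented, versioned reconstruction of the
# published examples ("##-year-old", "## yo", "YYYY-MM-DD", ...) extended
# with conventional clinical surface forms; the full original inventory was
# never published, so this table is deliberately a superset and lives in
# source control as the versioned rules artifact.

#' Subject term lexicon
#'
#' Kinship and non-kin subject terms recognized by [detect_subject()], with
#' their normalization category. An optional `maternal`/`paternal` modifier
#' is matched as part of the span but stripped for degree lookup.
#'
#' @return Data frame with columns `term`, `normalization`, `implicit`.
#' @export
subject_lexicon <- function() {
  kin <- c("identical twin", "grandmother", "grandfather", "granddaughter",
           "grandson", "half-brother", "half-sister", "mother", "father",
           "sister", "brother", "daughter", "son", "aunt", "uncle",
           "niece", "nephew", "cousin", "twin", "siblings", "sibling",
           "parents", "mom", "dad")
  data.frame(
    term = c(kin, "wife", "husband", "spouse", "donor",
             "family", "relatives", "relative"),
    normalization = c(rep("family_member", length(kin)),
                      "other", "other", "other", "donor_other",
                      "family_member", "family_member", "family_member"),
    implicit = c(rep(FALSE, length(kin) + 4L), TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Pattern rule table
#'
#' The regular-expression rules behind the rule-based recognizer, one row
#' per pattern family. `capture = TRUE` means the emitted span is capture
#' group 1 rather than the whole match (used to exclude context words such
#' as the preposition in "at age 69" or the possessive in "in his 70s").
#'
#' Deliberate exclusions, documented here because they are failure modes of
#' naive patterns: bare 4-digit years match only 1900-2099 (other numerics
#' such as medication quantities and room numbers follow similar shapes);
#' decade tokens like "70s" require a possessive/"age"/kin context (so the
#' "70s" inside "1970s" or a plural noun never fires); pack-year exposure
#' quantities ("30 pack-years") are not temporal expressions and no rule
#' matches them.
#'
#' @return Data frame with columns `class`, `family`, `regex`, `capture`,
#'   `type` (the attribute value the family assigns, `NA` for
#'   SUBJECT_CLASS).
#' @export
rule_patterns <- function() {
  months <- paste0("(?:January|February|March|April|May|June|July|August|",
                   "September|October|November|December|Jan|Feb|Mar|Apr|",
                   "Jun|Jul|Aug|Sept|Sep|Oct|Nov|Dec)")
  kin_ctx <- paste0("(?:mother|father|sister|brother|aunt|uncle|",
                    "grandmother|grandfather|cousin|son|daughter)")
  rbind(
    data.frame(class = "AGE", family = "fully-specified", capture = FALSE,
               type = "fully-specified", regex = c(
      "\\b\\d{1,3}[- ]?(?:year|yr)s?[- ]old\\b",
      "\\b\\d{1,3}\\s*(?:yo\\b|y/o|y\\.o\\.)")),
    data.frame(class = "AGE", family = "fully-specified", capture = TRUE,
               type = "fully-specified", regex =
      "\\b(?:at\\s+)?((?:age|aged)\\s+\\d{1,3})\\b"),
    data.frame(class = "AGE", family = "less-specified", capture = TRUE,
               type = "less-specified", regex = c(
      "\\b(?:in\\s+(?:his|her|their)\\s+|aged?\\s+)(\\d0s)\\b",
      sprintf("\\b%s\\s+(\\d0s)\\b", kin_ctx))),
    data.frame(class = "AGE", family = "event-specified", capture = FALSE,
               type = "event-specified", regex =
      "\\b(?:childhood|infancy|adolescence|teenager|teens)\\b"),
    data.frame(class = "TIMEX3", family = "calendar-date", capture = FALSE,
               type = "date", regex = c(
      "\\b\\d{4}-\\d{2}-\\d{2}\\b",
      "\\b\\d{1,2}/\\d{1,2}/\\d{4}\\b",
      "\\b\\d{1,2}/\\d{1,2}/\\d{2}\\b",
      sprintf("\\b%s\\.?\\s+\\d{4}\\b", months),
      "\\b(?:19|20)\\d{2}\\b")),
    data.frame(class = "TIMEX3", family = "relative-date", capture = FALSE,
               type = "date", regex = c(
      "\\b(?:next|last)\\s+(?:week|month|year)\\b",
      "\\b\\d+\\s+(?:day|week|month|year)s?\\s+ago\\b")),
    data.frame(class = "TIMEX3", family = "duration", capture = FALSE,
               type = "duration", regex = c(
      "\\bfor\\s+(?:\\d+|several|many)\\s+(?:day|week|month|year)s?\\b",
      "\\bx\\s*\\d+\\s+(?:day|week|month|year)s?\\b")),
    data.frame(class = "TIMEX3", family = "duration", capture = TRUE,
               type = "duration", regex =
      "\\b(\\d{1,3}[- ]year)\\s+(?:history|hx)\\b"),
    data.frame(class = "TIMEX3", family = "clock-time", capture = FALSE,
               type = "time", regex =
      "\\b\\d{1,2}:\\d{2}(?:\\s*(?:am|pm))?\\b")
  )
}

# All matches of one pattern over text, as 0-based absolute spans.
pattern_matches <- function(text, regex, capture, offset = 0L) {
  m <- gregexpr(regex, text, perl = TRUE, ignore.case = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  if (capture) {
    cs <- attr(m, "capture.start")[, 1L]
    cl <- attr(m, "capture.length")[, 1L]
    starts <- cs - 1L
    lens <- cl
  } else {
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
  }
  data.frame(start = offset + starts, end = offset + starts + lens,
             text = substring(text, starts + 1L, starts + lens),
             stringsAsFactors = FALSE)
}

# Longest-match-first, then leftmost, one-to-one span resolution within a
# class (standard maximal munch). Candidates must carry start/end.
resolve_spans <- function(cand, extra_order = NULL) {
  if (nrow(cand) == 0L) return(cand)
  len <- cand$end - cand$start
  ord <- if (is.null(extra_order)) order(-len, cand$start) else
    order(-len, -extra_order, cand$start)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  ends <- integer(0); starts <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- all(cand$start[i] >= ends | cand$end[i] <= starts)
    if (ok) {
      kept[i] <- TRUE
      starts <- c(starts, cand$start[i])
      ends <- c(ends, cand$end[i])
    }
  }
  out <- cand[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

detect_class_rules <- function(text, offset, class, rules) {
  rules <- rules[rules$class == class, , drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(rules))) {
    hits <- pattern_matches(text, rules$regex[i], rules$capture[i], offset)
    if (nrow(hits) > 0L) {
      hits$type <- rules$type[i]
      cand[[length(cand) + 1L]] <- hits
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand[, c("start", "end")]), , drop = FALSE]
  resolve_spans(cand)
}

spans_to_entities <- function(spans, class, attr_builder) {
  bind_entities(lapply(seq_len(nrow(spans)), function(i) {
    s <- spans[i, ]
    new_entity("PENDING", class, s$start, s$end, s$text,
               attrs = attr_builder(s))
  }))
}

#' Detect AGE mentions in a section
#'
#' Matches numeric age expressions ("61-year-old", "61 yo", "61yo",
#' "61 y/o", "age 69", "aged 54"), contextual decade expressions
#' ("in his 70s", "mother 70s" -- the span covers the decade token only),
#' and life-stage words ("childhood", "infancy", "adolescence", "teens").
#' The AGE `type` attribute is assigned by pattern family: `fully-specified`
#' for exact numerics, `less-specified` for decades, `event-specified` for
#' life-stage words. Leading prepositions are excluded from spans ("at age
#' 69" yields the span "age 69").
#'
#' @param text Section text (header plus body, or any slice of a note).
#' @param offset Absolute 0-based offset of `text` within its document.
#' @param rules Pattern table, by default [rule_patterns()].
#' @return Entity data frame (ids pending; see [run_rule_ner()]).
#' @export
#' @examples
#' detect_age("Father died of MI at age 69.")
detect_age <- function(text, offset = 0L, rules = rule_patterns()) {
  spans <- detect_class_rules(text, offset, "AGE", rules)
  spans_to_entities(spans, "AGE", function(s) list(type = s$type))
}

#' Detect TIMEX3 mentions in a section
#'
#' Matches calendar dates (`YYYY-MM-DD`, `MM/DD/YYYY`, `MM/DD/YY`,
#' "Month YYYY", bare years 1900-2099), relative date phrases ("next week",
#' "2 years ago"), durations ("for 10 years", "x 30 years", "10-year
#' history"), and clock times. The TIMEX3 `type` attribute (`date`, `time`,
#' `duration`) follows the pattern family. Pack-year exposure quantities
#' never match (they quantify exposure, not time).
#'
#' @inheritParams detect_age
#' @return Entity data frame.
#' @export
#' @examples
#' detect_timex("Arthroscopy in 1997")
detect_timex <- function(text, offset = 0L, rules = rule_patterns()) {
  spans <- detect_class_rules(text, offset, "TIMEX3", rules)
  spans_to_entities(spans, "TIMEX3", function(s) list(type = s$type))
}

#' Detect SUBJECT_CLASS mentions in a section
#'
#' Matches explicit kinship and non-kin subject terms from
#' [subject_lexicon()], including an optional `maternal`/`paternal` modifier
#' in the span. Emitted entities carry `normalization` (`family_member` for
#' kin, `other` for spouses, `donor_other` for donors), `degree_relation`
#' (via [degree_relation()]), and `implicit` (`true` for unspecified-subject
#' terms such as the "family" token of a family-history header, `false` for
#' direct mentions).
#'
#' @inheritParams detect_age
#' @param lexicon Subject term table, by default [subject_lexicon()].
#' @return Entity data frame.
#' @export
#' @examples
#' detect_subject("father had CAD")
detect_subject <- function(text, offset = 0L, lexicon = subject_lexicon()) {
  terms <- lexicon$term[order(-nchar(lexicon$term))]
  rx <- sprintf("\\b(?:(?:maternal|paternal)\\s+)?(?:%s)\\b",
                paste(regex_escape(terms), collapse = "|"))
  spans <- pattern_matches(text, rx, capture = FALSE, offset = offset)
  spans <- resolve_spans(spans)
  bind_entities(lapply(seq_len(nrow(spans)), function(i) {
    s <- spans[i, ]
    base <- tolower(sub("^(maternal|paternal)\\s+", "", tolower(s$text)))
    row <- lexicon[match(base, lexicon$term), ]
    new_entity("PENDING", "SUBJECT_CLASS", s$start, s$end, s$text,
               attrs = list(
                 normalization = row$normalization,
                 degree_relation = degree_relation(s$text),
                 implicit = if (row$implicit) "true" else "false"))
  }))
}

# Assign fresh sequential ids ("E<k>") to PENDING entities, continuing after
# any ids already present, in document (span) order.
assign_entity_ids <- function(entities, existing_ids = character(0)) {
  used <- suppressWarnings(as.integer(sub("^E", "", existing_ids)))
  nxt <- if (length(used) == 0L || all(is.na(used))) 1L else
    max(used, na.rm = TRUE) + 1L
  ord <- order(entities$start, entities$end, entities$class)
  entities <- entities[ord, , drop = FALSE]
  entities$id <- sprintf("E%d", seq_len(nrow(entities)) + nxt - 1L)
  rownames(entities) <- NULL
  entities
}

#' Run the rule-based recognizer over a document
#'
#' Applies [detect_age()], [detect_timex()], and [detect_subject()] to every
#' history section (header and body; `other` sections are never scanned, so
#' no emitted span falls outside a history section or crosses a section
#' boundary). Overlapping candidates of the same class are resolved
#' longest-match-first, then leftmost; duplicate spans are dropped. Detected
#' entities are appended to the document with fresh sequential ids.
#'
#' @param doc A `clinhist_document` (sections are tagged on demand).
#' @param rules Pattern table, by default [rule_patterns()].
#' @param subject_terms Subject term table, by default [subject_lexicon()].
#' @return The document with AGE/TIMEX3/SUBJECT_CLASS entities added.
#' @export
run_rule_ner <- function(doc, rules = rule_patterns(),
                         subject_terms = subject_lexicon()) {
  doc <- with_sections(doc)
  secs <- history_sections(doc$sections)
  found <- list()
  for (i in seq_len(nrow(secs))) {
    s <- secs[i, ]
    slice <- span_text(doc$text, s$header_start, s$body_end)
    off <- s$header_start
    found[[length(found) + 1L]] <- detect_age(slice, off, rules)
    found[[length(found) + 1L]] <- detect_timex(slice, off, rules)
    found[[length(found) + 1L]] <- detect_subject(slice, off, subject_terms)
  }
  ents <- bind_entities(found)
  if (nrow(ents) > 0L) {
    ents <- ents[!duplicated(ents[, c("class", "start", "end")]), ,
                 drop = FALSE]
    ents <- assign_entity_ids(ents, doc$entities$id)
    doc$entities <- bind_entities(doc$entities, ents)
  }
  doc
}
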