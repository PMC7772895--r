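# Approximate dictionary matcher for the medical classes DISEASE_DISORDER
# and PROCEDURE: candidate token windows are matched against a pluggable
# concept lexicon by character-trigram Jaccard similarity, and matches are
# routed to an entity class by the semantic type of the matched concept.

#' Normalize a term for dictionary matching
#'
#' Lowercases, strips punctuation except hyphens internal to tokens
#' (clinical compounds like "end-stage" stay one token), and collapses
#' whitespace.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9-]+", " ", x)
  x <- gsub("(^|\\s)-+|-+(\\s|$)", "\\1 \\2", x)  # strip edge hyphens
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Default stopword list for candidate windows
#'
#' Function words (and the `s`/`p` tokens of the clinical shorthand "s/p")
#' that candidate windows may not start or end on.
#'
#' @return Character vector.
#' @export
default_stoplist <- function() {
  c("the", "a", "an", "of", "with", "for", "and", "or", "in", "on", "at",
    "to", "is", "was", "were", "are", "has", "had", "have", "he", "she",
    "they", "his", "her", "their", "no", "not", "by", "from", "as", "s",
    "p", "status", "post")
}

# Token spans (0-based, absolute): alphanumeric runs, hyphens kept inside
# tokens.
tokenize_spans <- function(text, offset = 0L) {
  m <- gregexpr("[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*", text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(start = offset + starts, end = offset + starts + lens,
             text = substring(text, starts + 1L, starts + lens),
             stringsAsFactors = FALSE)
}

#' Candidate spans for dictionary matching
#'
#' All contiguous token windows of 1 to `max_tokens` tokens, excluding
#' windows that start or end on a stopword. Punctuation never enters a
#' window boundary because tokens are alphanumeric runs, and windows never
#' cross a line break (clinical history lists are line-structured;
#' sentence segmentation throughout the pipeline is line-based).
#'
#' @param text Section text.
#' @param max_tokens Maximum window length in tokens (default 6).
#' @param offset Absolute 0-based offset of `text` within its document.
#' @param stoplist Stopword vector, see [default_stoplist()].
#' @return Data frame of spans (`start`, `end`, `text`), absolute offsets.
#' @export
#' @examples
#' candidate_spans("end-stage renal disease", max_tokens = 3)
candidate_spans <- function(text, max_tokens = 6L, offset = 0L,
                            stoplist = default_stoplist()) {
  stopifnot(max_tokens >= 1L)
  toks <- tokenize_spans(text, offset)
  n <- nrow(toks)
  if (n == 0L) {
    return(toks)
  }
  stop_tok <- tolower(toks$text) %in% stoplist
  # line id of each token: windows may not span line breaks
  nl_pos <- gregexpr("\n", text, fixed = TRUE)[[1L]]
  nl_pos <- if (nl_pos[1L] == -1L) integer(0) else offset + nl_pos - 1L
  line_id <- findInterval(toks$start, nl_pos)
  out <- list()
  for (i in seq_len(n)) {
    if (stop_tok[i]) next
    for (len in seq_len(min(max_tokens, n - i + 1L))) {
      j <- i + len - 1L
      if (line_id[j] != line_id[i]) break
      if (stop_tok[j]) next
      out[[length(out) + 1L]] <- c(toks$start[i], toks$end[j])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  spans <- do.call(rbind, out)
  data.frame(start = spans[, 1L], end = spans[, 2L],
             text = substring(text, spans[, 1L] - offset + 1L,
                              spans[, 2L] - offset),
             stringsAsFactors = FALSE)
}

trigram_set <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(character(0))
  if (n < 3L) return(x)
  unique(substring(x, 1:(n - 2L), 3:n))
}

#' Character-trigram Jaccard similarity
#'
#' Jaccard coefficient over the sets of character trigrams of the two
#' normalized strings. Strings shorter than three characters contribute the
#' whole string as their single gram, so identical short strings still score
#' 1.
#'
#' @param a,b Strings (normalized with [normalize_term()] before gram
#'   extraction).
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' trigram_similarity("hysterectom", "hysterectomy")
trigram_similarity <- function(a, b) {
  ta <- trigram_set(normalize_term(a))
  tb <- trigram_set(normalize_term(b))
  u <- length(union(ta, tb))
  if (u == 0L) return(0)
  length(intersect(ta, tb)) / u
}

# Minimum normalized length for a string to take part in approximate
# matching; shorter strings (acronyms and other short forms) resolve only
# by exact lookup, since trigram similarity is meaningless for them.
MIN_APPROX_NCHAR <- 5L

#' Best lexicon match for a span
#'
#' Exact (normalized) matches score similarity 1. Otherwise the best entry
#' by character-trigram Jaccard similarity is returned, with ties broken by
#' preferred term then lexicographic concept id; `NULL` when the best
#' similarity falls below `threshold`. Short forms (under five normalized
#' characters, e.g. acronyms such as "CAD") and short lexicon entries match
#' exactly only -- approximate matching is not sensitive to short forms, so
#' abbreviation resolution is delegated to explicit synonym rows of the
#' lexicon.
#'
#' @param span_text Candidate surface string.
#' @param lexicon A `clinhist_lexicon`.
#' @param threshold Minimum similarity in `(0, 1]` (default 0.8).
#' @return List with `entry` (one-row entry data frame) and `similarity`,
#'   or `NULL`.
#' @export
#' @examples
#' match_term("Appendectomy", demo_lexicon())
match_term <- function(span_text, lexicon, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  entries <- lexicon$entries
  if (nrow(entries) == 0L) return(NULL)
  lexicon_matcher(lexicon, threshold)(span_text)
}

# Precompiled matcher closure: normalizes and indexes the lexicon once
# (exact-lookup hash plus per-entry trigram sets with a set-size Jaccard
# bound as prefilter), then matches each query with the same contract as
# match_term(). Used by run_lexicon_ner(), where thousands of candidate
# windows hit the same lexicon.
lexicon_matcher <- function(lexicon, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  entries <- lexicon$entries
  exact_idx <- split(seq_len(nrow(entries)), entries$norm)
  approx_rows <- which(nchar(entries$norm) >= MIN_APPROX_NCHAR)
  grams <- lapply(entries$norm[approx_rows], trigram_set)
  gsizes <- lengths(grams)
  pick <- function(rows, sims) {
    ord <- order(-sims, !entries$is_preferred[rows],
                 entries$concept_id[rows])
    list(entry = entries[rows[ord[1L]], , drop = FALSE],
         similarity = sims[ord[1L]])
  }
  function(span_text) {
    if (nrow(entries) == 0L) return(NULL)
    q <- normalize_term(span_text)
    if (!nzchar(q)) return(NULL)
    hit <- exact_idx[[q]]
    if (!is.null(hit)) return(pick(hit, rep(1, length(hit))))
    if (threshold >= 1 || nchar(q) < MIN_APPROX_NCHAR ||
        length(approx_rows) == 0L) {
      return(NULL)
    }
    qg <- trigram_set(q)
    nq <- length(qg)
    # |A n B| / |A u B| <= min(|A|,|B|) / max(|A|,|B|)
    ok <- pmin(nq, gsizes) / pmax(nq, gsizes) >= threshold
    if (!any(ok)) return(NULL)
    sims <- vapply(which(ok), function(k) {
      u <- length(union(qg, grams[[k]]))
      length(intersect(qg, grams[[k]])) / u
    }, numeric(1))
    best <- pick(approx_rows[ok], sims)
    if (best$similarity < threshold) return(NULL)
    best
  }
}

#' Semantic-type routing map
#'
#' Maps matched concepts to entity classes by their semantic type:
#' disorders (`T047` disease or syndrome, `T048` mental or behavioral
#' dysfunction, `T046` pathologic function, `T191` neoplastic process) to
#' `DISEASE_DISORDER`, and `T062` (therapeutic or preventative procedure) to
#' `PROCEDURE`. `T060` (diagnostic procedure) is excluded by default --
#' including it trades a large precision loss for extra recall -- but can be
#' added via a custom map. Concepts with unmapped types are never emitted.
#'
#' @return Named list: class -> character vector of semantic-type codes.
#' @export
default_semantic_map <- function() {
  list(
    DISEASE_DISORDER = c("T047", "T048", "T046", "T191"),
    PROCEDURE = "T062"
  )
}

#' Run the dictionary matcher over a document
#'
#' Generates candidate token windows over every history section, matches
#' them against the lexicon at the given similarity threshold, routes
#' matches to `DISEASE_DISORDER`/`PROCEDURE` via the semantic-type map
#' (unmapped types are dropped), and resolves overlapping matches by
#' longest span, then highest similarity, then leftmost. Emitted entities
#' carry the matched concept id as `associated_code` and a DocTimeRel
#' attribute filled from [default_doctimerel()].
#'
#' @param doc A `clinhist_document`.
#' @param lexicon A `clinhist_lexicon` (default: the demo lexicon).
#' @param threshold Similarity threshold in `(0, 1]` (default 0.8; at 1.0
#'   the matcher reduces to exact normalized-string dictionary matching).
#' @param max_tokens Maximum candidate window length (default 6).
#' @param semantic_map See [default_semantic_map()].
#' @param doctimerel Default table passed to [default_doctimerel()].
#' @return The document with DISEASE_DISORDER/PROCEDURE entities added.
#' @export
run_lexicon_ner <- function(doc, lexicon = demo_lexicon(), threshold = 0.8,
                            max_tokens = 6L,
                            semantic_map = default_semantic_map(),
                            doctimerel = doctimerel_defaults()) {
  doc <- with_sections(doc)
  secs <- history_sections(doc$sections)
  type_to_class <- character(0)
  for (cls in names(semantic_map)) {
    type_to_class[semantic_map[[cls]]] <- cls
  }
  matcher <- lexicon_matcher(lexicon, threshold)
  found <- list()
  for (i in seq_len(nrow(secs))) {
    s <- secs[i, ]
    slice <- span_text(doc$text, s$header_start, s$body_end)
    cand <- candidate_spans(slice, max_tokens, offset = s$header_start)
    for (k in seq_len(nrow(cand))) {
      hit <- matcher(cand$text[k])
      if (is.null(hit)) next
      cls <- type_to_class[hit$entry$semantic_type]
      if (is.na(cls)) next
      found[[length(found) + 1L]] <- data.frame(
        start = cand$start[k], end = cand$end[k], text = cand$text[k],
        class = unname(cls), concept_id = hit$entry$concept_id,
        similarity = hit$similarity, section = s$label,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(found) == 0L) return(doc)
  cand <- do.call(rbind, found)
  cand <- resolve_spans(cand, extra_order = cand$similarity)
  ents <- bind_entities(lapply(seq_len(nrow(cand)), function(k) {
    c0 <- cand[k, ]
    new_entity("PENDING", c0$class, c0$start, c0$end, c0$text,
               attrs = list(doctimerel = default_doctimerel(
                 c0$class, c0$section, doctimerel)),
               associated_code = c0$concept_id)
  }))
  ents <- assign_entity_ids(ents, doc$entities$id)
  doc$entities <- bind_entities(doc$entities, ents)
  doc
}
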