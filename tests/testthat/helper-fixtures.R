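# Fixture builders and independent oracles shared across the test files.

# --- incremental document builder with exact offset bookkeeping ---------

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$text <- ""
  env$ents <- list()
  env$rels <- list()
  env$k <- 0L
  env
}

emit <- function(b, txt) {
  b$text <- paste0(b$text, txt)
  invisible(NULL)
}

emit_ent <- function(b, txt, class, attrs = list(),
                     code = NA_character_) {
  start <- nchar(b$text)
  b$text <- paste0(b$text, txt)
  b$k <- b$k + 1L
  id <- sprintf("E%d", b$k)
  b$ents[[b$k]] <- new_entity(id, class, start, start + nchar(txt), txt,
                              attrs = attrs, associated_code = code)
  id
}

emit_rel <- function(b, source, target, type) {
  b$rels[[length(b$rels) + 1L]] <- new_relationship(source, target, type)
  invisible(NULL)
}

finish_doc <- function(b, doc_id, creation_date = NULL) {
  rels <- if (length(b$rels) == 0L) NULL else do.call(rbind, b$rels)
  new_document(doc_id, b$text, creation_date = creation_date,
               entities = bind_entities(b$ents),
               relationships = if (is.null(rels))
                 clinhist:::empty_relationships() else rels)
}

# --- the worked family-history example ---------------------------------

father_example_doc <- function() {
  b <- new_builder()
  emit(b, "Family History:\n")
  s <- emit_ent(b, "Father", "SUBJECT_CLASS",
                attrs = list(normalization = "family_member",
                             degree_relation = "1", implicit = "false"))
  emit(b, " ")
  oe <- emit_ent(b, "died", "OTHER_EVENTS",
                 attrs = list(type = "death", doctimerel = "before"))
  emit(b, " of ")
  dd <- emit_ent(b, "MI", "DISEASE_DISORDER",
                 attrs = list(doctimerel = "before"),
                 code = "C0027051")
  emit(b, " at ")
  a <- emit_ent(b, "age 69", "AGE", attrs = list(type = "fully-specified"))
  emit(b, ".\n")
  emit_rel(b, oe, s, "OE-to-S")
  emit_rel(b, dd, s, "DD-to-S")
  emit_rel(b, oe, a, "OE-to-A")
  finish_doc(b, "father-example", creation_date = as.Date("2014-03-01"))
}

# --- fixture corpora encoding the published table counts ----------------

# a document holding `counts[class]` minimal entities over filler text
count_doc <- function(doc_id, counts) {
  n <- sum(counts)
  text <- strrep("x", max(n, 1L))
  ents <- list()
  k <- 0L
  for (cl in names(counts)) {
    for (i in seq_len(counts[[cl]])) {
      k <- k + 1L
      ents[[k]] <- new_entity(sprintf("E%d", k), cl, k - 1L, k, "x")
    }
  }
  new_document(doc_id, text, entities = bind_entities(ents))
}

# spread total counts over n documents as evenly as possible
spread_counts <- function(totals, n_docs) {
  lapply(seq_len(n_docs), function(i) {
    vapply(totals, function(tot) {
      tot <- as.integer(tot)
      base <- tot %/% n_docs
      base + as.integer(i <= tot %% n_docs)
    }, integer(1))
  })
}

# corpus reproducing the full-corpus class marginals: 110 documents in
# development/train/test splits of 20/60/30 with per-split class counts
# 28/23/18/127/37/73, 76/60/32/373/71/174, and 36/36/24/188/53/111
table2_corpus <- function() {
  split_counts <- list(
    development = c(TIMEX3 = 28, AGE = 23, SUBJECT_CLASS = 18,
                    DISEASE_DISORDER = 127, PROCEDURE = 37,
                    OTHER_EVENTS = 73),
    train = c(TIMEX3 = 76, AGE = 60, SUBJECT_CLASS = 32,
              DISEASE_DISORDER = 373, PROCEDURE = 71, OTHER_EVENTS = 174),
    test = c(TIMEX3 = 36, AGE = 36, SUBJECT_CLASS = 24,
             DISEASE_DISORDER = 188, PROCEDURE = 53, OTHER_EVENTS = 111)
  )
  split_docs <- c(development = 20L, train = 60L, test = 30L)
  docs <- list()
  labels <- character(0)
  for (sp in names(split_counts)) {
    per_doc <- spread_counts(as.list(split_counts[[sp]]), split_docs[[sp]])
    for (i in seq_along(per_doc)) {
      id <- sprintf("%s%03d", sp, i)
      docs[[length(docs) + 1L]] <- count_doc(id, per_doc[[i]])
      labels[id] <- sp
    }
  }
  new_corpus(docs, split_labels = labels)
}

# corpus reproducing the training-set social-determinant counts
# (substance use 87, living situation 26, occupation 20, martial status 8,
# death 6, exposure 3, other 5)
table3_corpus <- function() {
  counts <- c("substance use" = 87, "living situation" = 26,
              "occupation" = 20, "martial status" = 8, "death" = 6,
              "exposure" = 3, "other" = 5)
  n <- sum(counts)
  text <- strrep("x", n)
  ents <- list(); k <- 0L
  for (type in names(counts)) {
    for (i in seq_len(counts[[type]])) {
      k <- k + 1L
      ents[[k]] <- new_entity(sprintf("E%d", k), "OTHER_EVENTS",
                              k - 1L, k, "x", attrs = list(type = type))
    }
  }
  new_corpus(list(new_document("sdoh", text,
                               entities = bind_entities(ents))))
}

# corpus reproducing the lung-cancer chart-review counts: per section,
# mention totals with date/age attachment, family-history degree and
# cancer-site breakdown, and the smoking-status partition
table4_corpus <- function() {
  b <- new_builder()
  dd <- function(term, code, timex = FALSE, age = FALSE) {
    emit_ent(b, term, "DISEASE_DISORDER", code = code)
    if (timex) {
      emit(b, " ")
      emit_ent(b, "03/04/2001", "TIMEX3", attrs = list(type = "date"))
    }
    if (age) {
      emit(b, " at ")
      emit_ent(b, "age 62", "AGE", attrs = list(type = "fully-specified"))
    }
    emit(b, "\n")
  }
  emit(b, "Past Medical History:\n")
  for (i in 1:23) dd("lung cancer", "C0684249")
  for (i in 1:12) dd("lung cancer", "C0684249", timex = TRUE)
  for (i in 1:16) dd("renal cancer", "C0740457")
  for (i in 1:20) dd("bladder cancer", "C0699885", timex = TRUE)
  for (i in 1:2) dd("prostate cancer", "C0033578", age = TRUE)
  emit(b, "Past Surgical History:\n")
  for (i in 1:18) {
    emit_ent(b, "wedge resection", "PROCEDURE", code = "C2939181")
    emit(b, "\n")
  }
  for (i in 1:34) {
    emit_ent(b, "lobectomy", "PROCEDURE", code = "C0259785")
    emit(b, " ")
    emit_ent(b, "05/06/2007", "TIMEX3", attrs = list(type = "date"))
    emit(b, "\n")
  }
  emit(b, "Social History:\n")
  smoke <- function(txt, doctimerel, negated = NULL) {
    at <- list(type = "substance use", doctimerel = doctimerel)
    if (!is.null(negated)) at$negated <- negated
    emit_ent(b, txt, "OTHER_EVENTS", attrs = at)
    emit(b, "\n")
  }
  for (i in 1:5) smoke("tobacco use: never", "unknown", negated = "true")
  for (i in 1:48) smoke("former smoker", "before")
  for (i in 1:13) smoke("current everyday smoker", "before_overlap")
  emit(b, "Family History:\n")
  fam <- function(term, code, kin, degree, age = FALSE) {
    emit_ent(b, term, "DISEASE_DISORDER", code = code)
    emit(b, " in ")
    emit_ent(b, kin, "SUBJECT_CLASS",
             attrs = list(normalization = "family_member",
                          degree_relation = degree, implicit = "false"))
    if (age) {
      emit(b, " ")
      emit_ent(b, "60s", "AGE", attrs = list(type = "less-specified"))
    }
    emit(b, "\n")
  }
  for (i in 1:2) fam("lung cancer", "C0684249", "sister", "1")
  for (i in 1:2) fam("lung cancer", "C0684249", "maternal uncle", "2")
  for (i in 1:2) fam("lung cancer", "C0684249", "maternal uncle", "2",
                     age = TRUE)
  for (i in 1:31) fam("ovarian cancer", "C0029925", "mother", "1")
  for (i in 1:15) fam("breast cancer", "C0006142", "maternal aunt", "2")
  for (i in 1:3) fam("breast cancer", "C0006142", "mother", "1",
                     age = TRUE)
  new_corpus(list(finish_doc(b, "chart-review")))
}

# --- independent oracles ------------------------------------------------

# brute-force character-trigram Jaccard via explicit set enumeration
oracle_trigram_jaccard <- function(a, b) {
  grams <- function(x) {
    x <- tolower(x)
    if (nchar(x) < 3L) return(unique(x))
    out <- character(0)
    for (i in seq_len(nchar(x) - 2L)) {
      out <- c(out, substr(x, i, i + 2L))
    }
    unique(out)
  }
  ga <- grams(a); gb <- grams(b)
  length(intersect(ga, gb)) / length(union(ga, gb))
}

# exhaustive maximum one-to-one matching size over overlap-compatible
# same-class pairs (oracle for the greedy pairing)
oracle_max_matching <- function(gold, system) {
  pairs <- list()
  for (i in seq_len(nrow(gold))) {
    for (j in seq_len(nrow(system))) {
      if (gold$class[i] != system$class[j]) next
      ov <- min(gold$end[i], system$end[j]) -
        max(gold$start[i], system$start[j])
      if (ov > 0L) pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (length(pairs) == 0L) return(0L)
  best <- 0L
  recurse <- function(idx, used_g, used_s, size) {
    if (size + (length(pairs) - idx + 1L) <= best) return()
    if (idx > length(pairs)) {
      best <<- max(best, size)
      return()
    }
    p <- pairs[[idx]]
    if (!(p[1L] %in% used_g) && !(p[2L] %in% used_s)) {
      recurse(idx + 1L, c(used_g, p[1L]), c(used_s, p[2L]), size + 1L)
    }
    recurse(idx + 1L, used_g, used_s, size)
    best <<- max(best, size)
  }
  recurse(1L, integer(0), integer(0), 0L)
  best
}

# naive exact dictionary scan: every lexicon term searched verbatim
# (word-bounded, case-insensitive) over the history sections, longest
# match winning -- the reference for the threshold-1.0 matcher
oracle_exact_scan <- function(doc, lexicon) {
  secs <- history_sections(tag_sections(doc$text))
  hits <- list()
  for (i in seq_len(nrow(secs))) {
    slice <- substr(doc$text, secs$header_start[i] + 1L, secs$body_end[i])
    for (k in seq_len(nrow(lexicon$entries))) {
      term <- lexicon$entries$term[k]
      rx <- paste0("\\b", clinhist:::regex_escape(term), "\\b")
      m <- gregexpr(rx, slice, ignore.case = TRUE, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      for (p in seq_along(m)) {
        st <- secs$header_start[i] + m[p] - 1L
        hits[[length(hits) + 1L]] <-
          data.frame(start = st, end = st + attr(m, "match.length")[p])
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  h <- do.call(rbind, hits)
  h <- h[!duplicated(h), , drop = FALSE]
  keep <- clinhist:::resolve_spans(h)
  keep[order(keep$start), c("start", "end")]
}

self_consistency_classes <- function() {
  c("AGE", "TIMEX3", "SUBJECT_CLASS", "DISEASE_DISORDER", "PROCEDURE")
}

annotate_bare <- function(doc, ...) {
  annotate_document(new_document(doc$doc_id, doc$text,
                                 creation_date = doc$creation_date), ...)
}
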