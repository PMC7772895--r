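# Descriptive statistics over annotated corpora: class distributions with
# per-document means, social-determinant (OTHER_EVENTS type) distributions,
# and per-section history summaries (age/date specification, family-history
# degree and cancer breakdown, smoking status).

#' Round half away from zero
#'
#' Commercial rounding (0.5 rounds up), used for all printed percentages
#' and per-document means; base R's `round()` rounds half to even, which
#' does not reproduce conventional table arithmetic.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  scale <- 10^digits
  # the 1e-9 guard absorbs binary representation error in values that are
  # mathematically exact halves (e.g. 1.005 stored as 1.00499...)
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

corpus_documents <- function(corpus, splits = NULL, exclude = NULL) {
  docs <- corpus$documents
  if (!is.null(splits) || !is.null(exclude)) {
    if (is.null(corpus$split_labels)) {
      stop("corpus has no split labels to filter on")
    }
    keep <- names(corpus$split_labels)
    if (!is.null(splits)) {
      keep <- keep[corpus$split_labels[keep] %in% splits]
    }
    if (!is.null(exclude)) {
      keep <- keep[!corpus$split_labels[keep] %in% exclude]
    }
    docs <- docs[names(docs) %in% keep]
  }
  docs
}

all_entities <- function(docs) {
  parts <- lapply(names(docs), function(id) {
    e <- docs[[id]]$entities
    if (nrow(e) == 0L) return(NULL)
    cbind(data.frame(doc_id = id, stringsAsFactors = FALSE), e)
  })
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0L) {
    return(cbind(data.frame(doc_id = character(0),
                            stringsAsFactors = FALSE), empty_entities()))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

distribution_table <- function(labels, total = NULL, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(labels))
  counts <- table(factor(labels, levels = levels))
  if (is.null(total)) total <- sum(counts)
  out <- data.frame(
    label = names(counts),
    count = as.integer(counts),
    percent = if (total > 0) round_half_up(100 * as.integer(counts) / total)
              else rep(NA_real_, length(counts)),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  class(out) <- c("clinhist_distribution", class(out))
  out
}

#' @export
print.clinhist_distribution <- function(x, ...) {
  cat(sprintf("<clinhist_distribution> total %d\n", attr(x, "total")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Entity-class distribution of a corpus
#'
#' Counts and integer-rounded percentages per entity class, plus the mean
#' number of mentions per document (2 decimal places) for each class.
#'
#' @param corpus A `clinhist_corpus`.
#' @param splits Optional split labels to keep (e.g.
#'   `c("development", "train", "test")`).
#' @param exclude Optional split labels to drop (e.g. `"holdout"`).
#' @return A `clinhist_distribution` data frame with columns `label`,
#'   `count`, `percent`, `per_document`; attributes `total` and
#'   `n_documents`.
#' @export
class_distribution <- function(corpus, splits = NULL, exclude = NULL) {
  docs <- corpus_documents(corpus, splits, exclude)
  if (length(docs) == 0L) stop("no documents selected")
  ents <- all_entities(docs)
  out <- distribution_table(ents$class, levels = unname(entity_classes()))
  out$per_document <- round_half_up(out$count / length(docs), 2L)
  attr(out, "n_documents") <- length(docs)
  out
}

#' Social-determinants-of-health distribution
#'
#' Counts and percentages of `OTHER_EVENTS` mentions by their `type`
#' attribute (substance use, living situation, occupation, martial status,
#' death, exposure, ...). A corpus without OTHER_EVENTS yields an empty
#' table.
#'
#' @param corpus A `clinhist_corpus`.
#' @param splits,exclude Optional split filters as in
#'   [class_distribution()].
#' @return A `clinhist_distribution` data frame.
#' @export
sdoh_distribution <- function(corpus, splits = NULL, exclude = NULL) {
  docs <- corpus_documents(corpus, splits, exclude)
  ents <- all_entities(docs)
  oe <- ents[ents$class == "OTHER_EVENTS", , drop = FALSE]
  types <- vapply(oe$attrs, function(a) {
    if (is.null(a$type)) NA_character_ else a$type
  }, character(1))
  types <- types[!is.na(types)]
  if (length(types) == 0L) {
    return(distribution_table(character(0)))
  }
  out <- distribution_table(types)
  out[order(-out$count, out$label), , drop = FALSE]
}

# Section label of each entity: the (unique) section containing its span.
entity_sections <- function(doc) {
  doc <- with_sections(doc)
  secs <- doc$sections
  vapply(seq_len(nrow(doc$entities)), function(i) {
    s <- doc$entities$start[i]
    hit <- which(secs$header_start <= s & s < secs$body_end)
    if (length(hit) == 0L) NA_character_ else secs$label[hit[1L]]
  }, character(1))
}

# 0-based [start, end) span of the text line containing offset `pos`.
line_span_at <- function(text, pos) {
  nl <- c(-1L, which(strsplit(text, "")[[1L]] == "\n") - 1L, nchar(text))
  lo <- max(nl[nl < pos | nl == -1L])
  hi <- min(nl[nl >= pos])
  c(lo + 1L, hi)
}

# Is entity i of doc linked to an AGE or a date-type TIMEX3? Linked means a
# relationship to such an entity, or -- when the document carries no
# relationships at all -- co-occurrence on the same text line.
has_age_or_date <- function(doc, i, want = c("AGE", "TIMEX3")) {
  ents <- doc$entities
  ok_partner <- function(j) {
    if (!ents$class[j] %in% want) return(FALSE)
    if (ents$class[j] == "TIMEX3") {
      return(identical(ents$attrs[[j]]$type, "date"))
    }
    TRUE
  }
  rels <- doc$relationships
  if (nrow(rels) > 0L) {
    id <- ents$id[i]
    partners <- c(rels$target[rels$source == id],
                  rels$source[rels$target == id])
    js <- match(partners, ents$id)
    return(any(vapply(js[!is.na(js)], ok_partner, logical(1))))
  }
  ln <- line_span_at(doc$text, ents$start[i])
  js <- which(ents$start >= ln[1L] & ents$start < ln[2L])
  js <- setdiff(js, i)
  any(vapply(js, ok_partner, logical(1)))
}

#' Default lung-cancer concept list
#'
#' Concept ids treated as lung-cancer diagnoses by [history_summary()];
#' all other cancer concepts count as "other cancer". Configurable.
#'
#' @return Character vector of concept ids.
#' @export
default_lung_cancer_concepts <- function() {
  c("C0684249", "C0007131")
}

#' Per-section history summary
#'
#' Descriptive summary of history mentions by section, in the layout used
#' for cohort chart review:
#'
#' * `sections`: per section, the count of relevant mentions
#'   (`DISEASE_DISORDER` in medical and family history, `PROCEDURE` in
#'   surgical history, substance-use `OTHER_EVENTS` in social history) and
#'   how many are age- or date-specified -- linked by a relationship to an
#'   `AGE` or a date-type `TIMEX3` entity, or, for documents without
#'   relationship annotations, co-occurring with one on the same text line.
#' * `family`: family-history disorder mentions partitioned into lung
#'   cancer versus other cancer (via the configurable concept list) and,
#'   within each, age-specified versus first-degree versus second-or-higher
#'   degree relative (degree from the linked or same-line subject).
#' * `smoking`: social-history substance-use mentions partitioned by
#'   negation flag and DocTimeRel: negated -> `never`, `before` -> former
#'   smoker, `before_overlap` -> current smoker.
#'
#' @param corpus A `clinhist_corpus`.
#' @param lung_concepts Concept ids counted as lung cancer.
#' @param splits,exclude Optional split filters.
#' @return List of class `clinhist_history_summary` with data frames
#'   `sections`, `family`, and `smoking` (counts with integer-rounded
#'   percentages of each table's total).
#' @export
history_summary <- function(corpus,
                            lung_concepts = default_lung_cancer_concepts(),
                            splits = NULL, exclude = NULL) {
  docs <- corpus_documents(corpus, splits, exclude)
  section_class <- c(past_medical_history = "DISEASE_DISORDER",
                     family_history = "DISEASE_DISORDER",
                     past_surgical_history = "PROCEDURE",
                     social_history = "OTHER_EVENTS")
  sec_counts <- stats::setNames(integer(4), names(section_class))
  sec_spec <- sec_counts
  fam <- character(0)
  smoke <- character(0)
  for (doc in docs) {
    doc <- with_sections(doc)
    labels <- entity_sections(doc)
    ents <- doc$entities
    for (i in seq_len(nrow(ents))) {
      lab <- labels[i]
      if (is.na(lab) || !lab %in% names(section_class)) next
      cls <- ents$class[i]
      a <- ents$attrs[[i]]
      if (lab == "social_history" && cls == "OTHER_EVENTS" &&
          identical(a$type, "substance use")) {
        sec_counts[lab] <- sec_counts[lab] + 1L
        if (has_age_or_date(doc, i)) sec_spec[lab] <- sec_spec[lab] + 1L
        smoke <- c(smoke, if (identical(a$negated, "true")) "never"
                   else if (identical(a$doctimerel, "before")) "before"
                   else if (identical(a$doctimerel, "before_overlap"))
                     "before_overlap" else "other")
        next
      }
      if (cls != section_class[[lab]]) next
      sec_counts[lab] <- sec_counts[lab] + 1L
      if (has_age_or_date(doc, i)) sec_spec[lab] <- sec_spec[lab] + 1L
      if (lab == "family_history" && cls == "DISEASE_DISORDER") {
        site <- if (!is.na(ents$associated_code[i]) &&
                    ents$associated_code[i] %in% lung_concepts) "lung"
                else "other"
        qual <- if (has_age_or_date(doc, i, want = "AGE")) "with_age"
                else {
                  deg <- linked_degree(doc, i)
                  if (identical(deg, "1")) "first_degree"
                  else "second_or_higher_degree"
                }
        fam <- c(fam, paste(site, qual, sep = "_"))
      }
    }
  }
  sections <- data.frame(
    section = names(sec_counts),
    total = as.integer(sec_counts),
    specified = as.integer(sec_spec),
    pct_specified = ifelse(sec_counts > 0,
                           round_half_up(100 * sec_spec / sec_counts),
                           NA_real_),
    stringsAsFactors = FALSE
  )
  out <- list(
    sections = sections,
    family = distribution_table(fam),
    smoking = distribution_table(smoke,
                                 levels = intersect(
                                   c("never", "before", "before_overlap",
                                     "other"), unique(smoke)))
  )
  class(out) <- "clinhist_history_summary"
  out
}

# degree_relation attribute of the subject linked to entity i (relationship
# preferred, same-line fallback); "unknown" when no subject is linked.
linked_degree <- function(doc, i) {
  ents <- doc$entities
  rels <- doc$relationships
  js <- integer(0)
  if (nrow(rels) > 0L) {
    id <- ents$id[i]
    partners <- c(rels$target[rels$source == id],
                  rels$source[rels$target == id])
    js <- match(partners, ents$id)
    js <- js[!is.na(js)]
  } else {
    ln <- line_span_at(doc$text, ents$start[i])
    js <- which(ents$start >= ln[1L] & ents$start < ln[2L])
    js <- setdiff(js, i)
  }
  js <- js[ents$class[js] == "SUBJECT_CLASS"]
  if (length(js) == 0L) return("unknown")
  deg <- ents$attrs[[js[1L]]]$degree_relation
  if (is.null(deg)) "unknown" else deg
}

#' @export
print.clinhist_history_summary <- function(x, ...) {
  cat("<clinhist_history_summary>\n-- sections --\n")
  print(x$sections, row.names = FALSE)
  cat("-- family history --\n")
  print(as.data.frame(x$family), row.names = FALSE)
  cat("-- smoking status --\n")
  print(as.data.frame(x$smoking), row.names = FALSE)
  invisible(x)
}
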