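#' Entity classes of the expanded history-annotation schema
#'
#' The schema covers six named-entity (NE) classes over the history sections
#' of clinical notes: the TimeML-derived temporal class `TIMEX3`, the subject
#' class `SUBJECT_CLASS` (any subject who is not the patient, including
#' implicit mentions), the disorder class `DISEASE_DISORDER`, plus the three
#' history-oriented classes `AGE`, `PROCEDURE`, and `OTHER_EVENTS` (social
#' determinants of health and other clinically relevant life events).
#'
#' @return Named character vector mapping the short serialized tag
#'   (`A`, `T`, `S`, `DD`, `P`, `OE`) to the full class name.
#' @export
#' @examples
#' entity_classes()[["DD"]]
entity_classes <- function() {
  c(
    A  = "AGE",
    T  = "TIMEX3",
    S  = "SUBJECT_CLASS",
    DD = "DISEASE_DISORDER",
    P  = "PROCEDURE",
    OE = "OTHER_EVENTS"
  )
}

#' Short tag for an entity class name
#' @param class Full entity class name, e.g. `"DISEASE_DISORDER"`.
#' @return The serialized tag, e.g. `"DD"`.
#' @export
class_tag <- function(class) {
  cls <- entity_classes()
  tags <- stats::setNames(names(cls), cls)
  unname(tags[class])
}

# DocTimeRel values: temporal relation between an event and the document
# creation time.
doctimerel_values <- function() {
  c("after", "overlap", "before_overlap", "before", "unknown")
}

#' Attribute vocabularies per entity class
#'
#' Closed attribute-value sets for each entity class. Every attribute carried
#' by an entity must be listed here for its class and hold one of the listed
#' values; [validate_document()] rejects anything else.
#'
#' * `AGE$type`: `fully-specified` (exact numeric age), `less-specified`
#'   (e.g. a decade such as "70s"), `event-specified` (a life stage such as
#'   "childhood").
#' * `TIMEX3$type`: `date`, `time`, `duration`.
#' * `SUBJECT_CLASS$normalization`: `family_member`, `donor_other`,
#'   `donor_family_member`, `other`; `degree_relation`: degree of biological
#'   relation (`0` identical twin, `1` parent/sibling/offspring, `2`, `3`,
#'   `not_biologically_related`, `unknown`); `implicit`: `true`/`false`.
#' * `DISEASE_DISORDER`, `PROCEDURE`: `doctimerel`.
#' * `OTHER_EVENTS`: `type` (social-determinant categories; the value
#'   `martial status` is the canonical token as published, with
#'   `marital status` accepted as an input alias), `doctimerel`, and an
#'   optional input flag `negated` (`true`/`false`) carried by upstream
#'   assertion annotation, e.g. "Tobacco use: never".
#'
#' All attribute values are stored as strings (degree of relation included),
#' so documents round-trip through the JSON standoff format unchanged.
#'
#' @return Named list: class name -> (attribute name -> character vector of
#'   allowed values).
#' @export
attribute_schema <- function() {
  list(
    AGE = list(
      type = c("fully-specified", "less-specified", "event-specified")
    ),
    TIMEX3 = list(
      type = c("date", "time", "duration")
    ),
    SUBJECT_CLASS = list(
      normalization = c("family_member", "donor_other",
                        "donor_family_member", "other"),
      degree_relation = c("0", "1", "2", "3",
                          "not_biologically_related", "unknown"),
      implicit = c("true", "false")
    ),
    DISEASE_DISORDER = list(
      doctimerel = doctimerel_values()
    ),
    PROCEDURE = list(
      doctimerel = doctimerel_values()
    ),
    OTHER_EVENTS = list(
      type = c("martial status", "death", "good health", "substance use",
               "occupation", "exposure", "living situation",
               "outcome of procedures", "other"),
      doctimerel = doctimerel_values(),
      negated = c("true", "false")
    )
  )
}

# Legal ordered relation-type pairs, inferred from the worked family-history
# example ("Father died of MI at age 69") and entity semantics: events link to
# their subject, age, and time.
legal_relation_types <- function() {
  c("OE-to-S", "DD-to-S", "P-to-S",
    "OE-to-A", "DD-to-A", "P-to-A",
    "OE-to-T", "DD-to-T", "P-to-T")
}

# Canonical empty entity table. Offsets are 0-based, half-open: the span
# covers text[start, end) and its length is end - start.
empty_entities <- function() {
  out <- data.frame(
    id = character(0),
    class = character(0),
    start = integer(0),
    end = integer(0),
    text = character(0),
    associated_code = character(0),
    stringsAsFactors = FALSE
  )
  out$attrs <- list()
  out
}

empty_relationships <- function() {
  data.frame(
    source = character(0),
    target = character(0),
    type = character(0),
    stringsAsFactors = FALSE
  )
}

# Accept published-vocabulary aliases on input.
canonicalize_attrs <- function(class, attrs) {
  if (class == "OTHER_EVENTS" && !is.null(attrs$type) &&
      identical(attrs$type, "marital status")) {
    attrs$type <- "martial status"
  }
  attrs
}

#' Construct a named entity
#'
#' @param id Entity id, unique within its document (convention: `"E1"`,
#'   `"E2"`, ... in document order).
#' @param class Entity class name (see [entity_classes()]).
#' @param start,end 0-based half-open character offsets into the document
#'   text.
#' @param text The covered substring.
#' @param attrs Named list of attribute values (see [attribute_schema()]).
#' @param associated_code Optional concept id (CUI-like string), allowed for
#'   `DISEASE_DISORDER`, `PROCEDURE`, and substance-use `OTHER_EVENTS` only.
#' @return A one-row entity data frame; rows from several calls can be
#'   combined with [bind_entities()].
#' @export
#' @examples
#' new_entity("E1", "AGE", 24, 30, "age 69",
#'            attrs = list(type = "fully-specified"))
new_entity <- function(id, class, start, end, text,
                       attrs = list(), associated_code = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L,
            class %in% entity_classes())
  out <- data.frame(
    id = id,
    class = class,
    start = as.integer(start),
    end = as.integer(end),
    text = text,
    associated_code = as.character(associated_code),
    stringsAsFactors = FALSE
  )
  out$attrs <- list(canonicalize_attrs(class, attrs))
  out
}

#' Combine entity rows
#' @param ... One-row entity frames (or a single list of them).
#' @return A combined entity data frame.
#' @export
bind_entities <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !is.data.frame(parts[[1L]])) {
    parts <- parts[[1L]]
  }
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, parts)
  if (length(parts) == 0L) return(empty_entities())
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Construct a relationship row
#'
#' A typed, directed link between two entities of one document; `type` is the
#' ordered class-tag pair, e.g. `"DD-to-S"` for a disorder linked to its
#' subject.
#'
#' @param source,target Entity ids.
#' @param type Relation type string, `"<tag>-to-<tag>"`.
#' @return One-row relationship data frame.
#' @export
new_relationship <- function(source, target, type) {
  data.frame(source = source, target = target, type = type,
             stringsAsFactors = FALSE)
}

#' Construct an annotated document
#'
#' @param doc_id Document identifier.
#' @param text Full note text (offsets index into it; never normalized).
#' @param creation_date Optional document creation [Date]; anchors the
#'   DocTimeRel attribute and age-to-time-range normalization.
#' @param sections Optional section table from [tag_sections()]; computed
#'   on demand by functions that need it when `NULL`.
#' @param entities Entity table (see [new_entity()]).
#' @param relationships Relationship table (see [new_relationship()]).
#' @return Object of class `clinhist_document`.
#' @export
new_document <- function(doc_id, text, creation_date = NULL,
                         sections = NULL,
                         entities = empty_entities(),
                         relationships = empty_relationships()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  if (!is.null(creation_date)) creation_date <- as.Date(creation_date)
  structure(
    list(doc_id = doc_id, text = text, creation_date = creation_date,
         sections = sections, entities = entities,
         relationships = relationships),
    class = "clinhist_document"
  )
}

#' @export
print.clinhist_document <- function(x, ...) {
  cat(sprintf("<clinhist_document> %s\n", x$doc_id))
  cat(sprintf("  text: %d chars; creation date: %s\n", nchar(x$text),
              if (is.null(x$creation_date)) "none" else
                format(x$creation_date)))
  if (!is.null(x$sections)) {
    cat(sprintf("  sections: %s\n",
                paste(x$sections$label, collapse = ", ")))
  }
  cat(sprintf("  entities: %d", nrow(x$entities)))
  if (nrow(x$entities) > 0L) {
    tab <- table(x$entities$class)
    cat(" (", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat(sprintf("\n  relationships: %d\n", nrow(x$relationships)))
  invisible(x)
}

#' Construct a corpus of annotated documents
#'
#' @param documents List of `clinhist_document` objects.
#' @param split_labels Optional named character vector, doc_id ->
#'   `development` / `train` / `test` / `holdout`; must cover exactly the
#'   corpus documents when present.
#' @return Object of class `clinhist_corpus`.
#' @export
new_corpus <- function(documents, split_labels = NULL) {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  stopifnot(!anyDuplicated(ids))
  names(documents) <- ids
  if (!is.null(split_labels)) {
    stopifnot(setequal(names(split_labels), ids),
              all(split_labels %in% c("development", "train", "test",
                                      "holdout")))
  }
  structure(list(documents = documents, split_labels = split_labels),
            class = "clinhist_corpus")
}

#' @export
print.clinhist_corpus <- function(x, ...) {
  n_ent <- sum(vapply(x$documents, function(d) nrow(d$entities), integer(1)))
  cat(sprintf("<clinhist_corpus> %d documents, %d entities\n",
              length(x$documents), n_ent))
  if (!is.null(x$split_labels)) {
    tab <- table(factor(x$split_labels,
                        levels = c("development", "train", "test",
                                   "holdout")))
    cat("  splits:", paste(sprintf("%s %d", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

# substr over a 0-based half-open span
span_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

#' Validate an annotated document against the schema
#'
#' Checks span bounds and text fidelity, entity-id uniqueness, class and
#' attribute vocabularies (attributes present must be exactly ones allowed
#' for the class, with in-vocabulary values), the `associated_code`
#' restriction (disorders, procedures, and substance-use other-events only),
#' and relationship integrity (both endpoints exist; the relation type equals
#' the ordered tag pair of its endpoint classes and is one of the legal
#' pairs).
#'
#' @param doc A `clinhist_document`.
#' @return Character vector of violation descriptions; empty when the
#'   document is valid. Violations are returned, never raised, and the call
#'   has no side effects.
#' @export
#' @examples
#' d <- new_document("d1", "Patient had childhood diabetes",
#'   entities = new_entity("E1", "AGE", 12, 21, "childhood",
#'                         attrs = list(type = "event-specified")))
#' validate_document(d)  # character(0)
validate_document <- function(doc) {
  stopifnot(inherits(doc, "clinhist_document"))
  v <- character(0)
  ents <- doc$entities
  schema <- attribute_schema()
  n <- nchar(doc$text)

  if (anyDuplicated(ents$id)) {
    dup <- unique(ents$id[duplicated(ents$id)])
    v <- c(v, sprintf("entity %s: id: duplicated entity id", dup))
  }
  for (i in seq_len(nrow(ents))) {
    e <- ents[i, ]
    at <- e$attrs[[1L]]
    if (!e$class %in% entity_classes()) {
      v <- c(v, sprintf("entity %s: class: unknown entity class '%s'",
                        e$id, e$class))
      next
    }
    if (is.na(e$start) || is.na(e$end) || e$start < 0L || e$start >= e$end ||
        e$end > n) {
      v <- c(v, sprintf(
        "entity %s: span: offsets [%s,%s) out of bounds for text of %d chars",
        e$id, e$start, e$end, n))
    } else if (!identical(span_text(doc$text, e$start, e$end), e$text)) {
      v <- c(v, sprintf(
        "entity %s: span: text '%s' does not match document substring '%s'",
        e$id, e$text, span_text(doc$text, e$start, e$end)))
    }
    allowed <- schema[[e$class]]
    for (nm in names(at)) {
      if (!nm %in% names(allowed)) {
        v <- c(v, sprintf(
          "entity %s: attributes: attribute '%s' not allowed for class %s",
          e$id, nm, e$class))
      } else if (!as.character(at[[nm]]) %in% allowed[[nm]]) {
        v <- c(v, sprintf(
          "entity %s: attributes: value '%s' not in vocabulary of %s.%s",
          e$id, as.character(at[[nm]]), e$class, nm))
      }
    }
    if (!is.na(e$associated_code)) {
      code_ok <- e$class %in% c("DISEASE_DISORDER", "PROCEDURE") ||
        (e$class == "OTHER_EVENTS" && identical(at$type, "substance use"))
      if (!code_ok) {
        v <- c(v, sprintf(
          paste0("entity %s: associated_code: only allowed for ",
                 "DISEASE_DISORDER, PROCEDURE, and substance-use ",
                 "OTHER_EVENTS"), e$id))
      }
    }
  }

  rels <- doc$relationships
  tags <- stats::setNames(names(entity_classes()), entity_classes())
  for (i in seq_len(nrow(rels))) {
    r <- rels[i, ]
    src <- match(r$source, ents$id)
    tgt <- match(r$target, ents$id)
    if (is.na(src) || is.na(tgt)) {
      v <- c(v, sprintf(
        "relationship %s->%s: endpoint: references a missing entity id",
        r$source, r$target))
      next
    }
    want <- sprintf("%s-to-%s", tags[[ents$class[src]]],
                    tags[[ents$class[tgt]]])
    if (!identical(r$type, want)) {
      v <- c(v, sprintf(
        "relationship %s->%s: type: '%s' does not match endpoint classes (%s)",
        r$source, r$target, r$type, want))
    } else if (!want %in% legal_relation_types()) {
      v <- c(v, sprintf(
        "relationship %s->%s: type: '%s' is not a legal relation pair",
        r$source, r$target, r$type))
    }
  }
  v
}
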