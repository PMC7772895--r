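#' Read a clinical note file
#'
#' Reads a plain-text note, preserving its content byte-for-byte (offsets of
#' standoff annotations depend on it, so no whitespace normalization is ever
#' applied). If the first line is a header of the form `DATE: YYYY-MM-DD`,
#' it is parsed as the document creation date and the text starts at the
#' following line.
#'
#' @param path Path to a UTF-8 text file.
#' @param doc_id Document id; defaults to the file name without extension.
#' @return A list with `doc_id`, `text`, and `creation_date` (`NULL` when no
#'   header is present).
#' @export
read_note <- function(path, doc_id = NULL) {
  if (!file.exists(path)) stop("note file not found: ", path)
  raw <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  if (!validUTF8(raw)) stop("note file is not valid UTF-8: ", path)
  if (is.null(doc_id)) doc_id <- sub("\\.[^.]*$", "", basename(path))
  creation_date <- NULL
  text <- raw
  m <- regmatches(raw, regexec("^DATE: (\\d{4}-\\d{2}-\\d{2})\\r?\\n", raw))[[1]]
  if (length(m) == 2L) {
    creation_date <- as.Date(m[2])
    text <- substr(raw, nchar(m[1]) + 1L, nchar(raw))
  }
  list(doc_id = doc_id, text = text, creation_date = creation_date)
}

# Ordered, deterministic JSON representation of a document. Field order and
# formatting are fixed so that serialization round-trips byte-identically.
document_to_json <- function(doc) {
  empty_obj <- stats::setNames(list(), character(0))
  ent_list <- lapply(seq_len(nrow(doc$entities)), function(i) {
    e <- doc$entities[i, ]
    out <- list(id = e$id, class = e$class,
                start = e$start, end = e$end, text = e$text,
                attributes = if (length(e$attrs[[1L]]) == 0L) empty_obj
                             else e$attrs[[1L]])
    if (!is.na(e$associated_code)) out$associated_code <- e$associated_code
    out
  })
  rel_list <- lapply(seq_len(nrow(doc$relationships)), function(i) {
    r <- doc$relationships[i, ]
    list(source = r$source, target = r$target, type = r$type)
  })
  sec_list <- if (is.null(doc$sections)) list() else
    lapply(seq_len(nrow(doc$sections)), function(i) {
      s <- doc$sections[i, ]
      list(label = s$label,
           header_start = s$header_start, header_end = s$header_end,
           body_start = s$body_start, body_end = s$body_end)
    })
  obj <- list(doc_id = doc$doc_id)
  if (!is.null(doc$creation_date)) {
    obj$creation_date <- format(doc$creation_date, "%Y-%m-%d")
  }
  obj$text <- doc$text
  obj$sections <- sec_list
  obj$entities <- ent_list
  obj$relationships <- rel_list
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = 2, digits = NA)
}

#' Write a document as JSON standoff
#'
#' Serializes an annotated document to the package's JSON standoff dialect:
#' top-level keys `doc_id`, `creation_date` (optional), `text`, `sections`,
#' `entities` (each with `id`, `class`, `start`, `end`, `text`,
#' `attributes`, optional `associated_code`), and `relationships` (each with
#' `source`, `target`, `type`). Serialization is deterministic;
#' write -> read -> write is byte-identical for valid documents.
#'
#' @param doc A valid `clinhist_document`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(doc, path) {
  v <- validate_document(doc)
  if (length(v) > 0L) {
    stop("document fails validation:\n  ", paste(v, collapse = "\n  "))
  }
  writeLines(document_to_json(doc), path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON standoff annotation file
#'
#' Parses the dialect written by [write_annotations()]. Unknown fields are
#' rejected, and the reconstructed document must pass [validate_document()]
#' (in particular, every entity's recorded text must equal the document
#' substring at its offsets, and relationships must reference existing
#' entities).
#'
#' @param path Path to a standoff JSON file.
#' @return A `clinhist_document`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  allowed <- c("doc_id", "creation_date", "text", "sections", "entities",
               "relationships")
  extra <- setdiff(names(obj), allowed)
  if (length(extra) > 0L) {
    stop("unknown top-level fields in standoff file: ",
         paste(extra, collapse = ", "))
  }
  for (k in c("doc_id", "text")) {
    if (is.null(obj[[k]])) stop("standoff file missing required field: ", k)
  }
  ent_allowed <- c("id", "class", "start", "end", "text", "attributes",
                   "associated_code")
  ents <- bind_entities(lapply(obj$entities, function(e) {
    extra <- setdiff(names(e), ent_allowed)
    if (length(extra) > 0L) {
      stop("unknown entity fields: ", paste(extra, collapse = ", "))
    }
    new_entity(e$id, e$class, e$start, e$end, e$text,
               attrs = lapply(e$attributes, as.character),
               associated_code = if (is.null(e$associated_code))
                 NA_character_ else e$associated_code)
  }))
  rels <- if (length(obj$relationships) == 0L) empty_relationships() else
    do.call(rbind, lapply(obj$relationships, function(r) {
      new_relationship(r$source, r$target, r$type)
    }))
  secs <- NULL
  if (length(obj$sections) > 0L) {
    secs <- do.call(rbind, lapply(obj$sections, function(s) {
      data.frame(label = s$label,
                 header_start = as.integer(s$header_start),
                 header_end = as.integer(s$header_end),
                 body_start = as.integer(s$body_start),
                 body_end = as.integer(s$body_end),
                 stringsAsFactors = FALSE)
    }))
  }
  doc <- new_document(obj$doc_id, obj$text,
                      creation_date = obj$creation_date,
                      sections = secs, entities = ents,
                      relationships = rels)
  v <- validate_document(doc)
  if (length(v) > 0L) {
    stop("standoff file fails validation:\n  ",
         paste(v, collapse = "\n  "))
  }
  doc
}

#' Read a concept lexicon from TSV
#'
#' Loads a 4-column tab-separated lexicon: `concept_id` (CUI-like string),
#' `term` (surface form), `semantic_type` (UMLS-style T-code, `T` + 3
#' digits), `is_preferred` (1 for the preferred term of a concept, 0 for a
#' synonym). Terms are indexed under a normalized form (lowercase,
#' punctuation stripped except internal hyphens, whitespace collapsed) while
#' the original surface is kept.
#'
#' @param path Path to the TSV file (header row required).
#' @return Object of class `clinhist_lexicon` with an `entries` data frame
#'   carrying a `norm` column.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("concept_id", "term", "semantic_type", "is_preferred")
  if (!identical(names(df), need)) {
    stop("lexicon must have exactly the columns: ",
         paste(need, collapse = ", "))
  }
  if (nrow(df) > 0L) {
    if (any(!nzchar(df$term))) stop("lexicon contains an empty term")
    bad <- !grepl("^T\\d{3}$", df$semantic_type)
    if (any(bad)) {
      stop("invalid semantic_type code(s): ",
           paste(unique(df$semantic_type[bad]), collapse = ", "))
    }
  }
  df$is_preferred <- df$is_preferred == "1"
  df$norm <- normalize_term(df$term)
  structure(list(entries = df), class = "clinhist_lexicon")
}

#' @export
print.clinhist_lexicon <- function(x, ...) {
  cat(sprintf("<clinhist_lexicon> %d terms, %d concepts\n",
              nrow(x$entries), length(unique(x$entries$concept_id))))
  invisible(x)
}

#' Exact lookup of a term in a lexicon
#'
#' Case-insensitive (normalized-form) lookup; returns all entry rows whose
#' normalized term equals the normalized query.
#'
#' @param lexicon A `clinhist_lexicon`.
#' @param term Surface string to look up.
#' @return Data frame of matching entries (possibly empty).
#' @export
lexicon_lookup <- function(lexicon, term) {
  hits <- lexicon$entries[lexicon$entries$norm == normalize_term(term), ,
                          drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Demo concept lexicon
#'
#' A small lexicon of common disorders, procedures, and substance-use
#' concepts shipped with the package so that examples and fixtures resolve
#' concept codes without access to a licensed terminology. Codes are
#' CUI-like identifier strings; a handful of acronym synonym rows (CAD, MI,
#' HTN, CABG, ...) are included so that short forms resolve by exact lookup.
#'
#' @return A `clinhist_lexicon`.
#' @export
demo_lexicon <- function() {
  read_lexicon(system.file("extdata", "demo_lexicon.tsv",
                           package = "clinhist", mustWork = TRUE))
}
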