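# End-to-end pipeline: section tagging -> rule-based NER (AGE, TIMEX3,
# SUBJECT_CLASS) -> dictionary NER (DISEASE_DISORDER, PROCEDURE) with
# defaulted attributes -> standoff JSON. Sentence segmentation is
# line-based within sections: clinical history lists are line-structured,
# and every implemented rule operates within a line.

#' Annotate a document with the full NER pipeline
#'
#' Tags sections, runs the rule-based recognizer and the dictionary
#' matcher over the history sections, and returns the document with all
#' extracted entities (attributes filled from the pattern families and the
#' DocTimeRel default table). The result always passes
#' [validate_document()].
#'
#' @param doc A `clinhist_document` (typically from [read_note()] output
#'   via [new_document()]); pre-existing entities are kept and extracted
#'   ones appended after them.
#' @param lexicon Concept lexicon for the dictionary matcher.
#' @param threshold Dictionary similarity threshold.
#' @param max_tokens Dictionary candidate window size.
#' @param keywords Section keyword table.
#' @param rules Pattern rule table.
#' @param semantic_map Semantic-type routing map.
#' @return The annotated `clinhist_document`.
#' @export
#' @examples
#' doc <- new_document("ex", "Family History:\nFather died of MI at age 69.\n")
#' annotate_document(doc)
annotate_document <- function(doc, lexicon = demo_lexicon(),
                              threshold = 0.8, max_tokens = 6L,
                              keywords = default_section_keywords(),
                              rules = rule_patterns(),
                              semantic_map = default_semantic_map()) {
  doc <- with_sections(doc, keywords)
  doc <- run_rule_ner(doc, rules)
  doc <- run_lexicon_ner(doc, lexicon, threshold, max_tokens, semantic_map)
  doc
}

#' Run the pipeline over note files
#'
#' Reads each note (optional `DATE:` header), annotates it, and writes a
#' standoff JSON file next to the requested output directory. Unreadable
#' or failing inputs are reported and skipped; processing continues for
#' the remaining files.
#'
#' @param note_paths Character vector of note file paths.
#' @param out_dir Output directory for `<doc_id>.json` files.
#' @param ... Passed to [annotate_document()].
#' @return Invisibly, a summary data frame with one row per input:
#'   `doc_id`, `path`, `status` (`ok`/`error`), `message`, and per-class
#'   entity counts; attribute `n_failed` carries the failure count.
#' @export
run_pipeline <- function(note_paths, out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  classes <- unname(entity_classes())
  rows <- lapply(note_paths, function(path) {
    res <- tryCatch({
      note <- read_note(path)
      doc <- new_document(note$doc_id, note$text,
                          creation_date = note$creation_date)
      doc <- annotate_document(doc, ...)
      write_annotations(doc, file.path(out_dir,
                                       paste0(doc$doc_id, ".json")))
      counts <- table(factor(doc$entities$class, levels = classes))
      c(list(doc_id = doc$doc_id, path = path, status = "ok",
             message = ""), as.list(as.integer(counts)))
    }, error = function(e) {
      c(list(doc_id = sub("\\.[^.]*$", "", basename(path)), path = path,
             status = "error", message = conditionMessage(e)),
        as.list(rep(NA_integer_, length(classes))))
    })
    names(res)[5:10] <- classes
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- sum(out$status == "error")
  for (i in which(out$status == "error")) {
    message(sprintf("pipeline: %s failed: %s", out$path[i], out$message[i]))
  }
  invisible(out)
}
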