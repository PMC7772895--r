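#' Default section keyword table
#'
#' Header phrases recognized for each history section. Full phrases match at
#' the start of a line (after optional whitespace), optionally followed by
#' `":"`, with the rest of the line belonging to the section body.
#' Abbreviation entries (`whole_line = TRUE`: PMH, PSH, FH, SH) match only
#' when the entire line is the abbreviation, optionally with a colon --
#' otherwise short header tokens would fire inside narrative text.
#'
#' @return Data frame with columns `label`, `phrase`, `whole_line`.
#' @export
default_section_keywords <- function() {
  kw <- rbind(
    data.frame(label = "past_surgical_history",
               phrase = c("past surgical history", "surgical history"),
               whole_line = FALSE),
    data.frame(label = "past_medical_history",
               phrase = c("past medical history", "medical history"),
               whole_line = FALSE),
    data.frame(label = "family_history",
               phrase = "family history", whole_line = FALSE),
    data.frame(label = "social_history",
               phrase = "social history", whole_line = FALSE),
    data.frame(label = c("past_medical_history", "past_surgical_history",
                         "family_history", "social_history"),
               phrase = c("pmh", "psh", "fh", "sh"),
               whole_line = TRUE)
  )
  kw
}

#' Read a section keyword table from a config file
#'
#' One phrase per line, label-prefixed: `label: phrase`. Phrases of three
#' characters or fewer are treated as whole-line abbreviations.
#'
#' @param path Path to the config file.
#' @return Keyword table in the format of [default_section_keywords()].
#' @export
read_section_keywords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- regmatches(lines, regexec("^([a-z_]+)\\s*:\\s*(.+)$", lines))
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) stop("malformed keyword line(s): ",
                     paste(lines[bad], collapse = "; "))
  data.frame(
    label = vapply(parts, `[`, character(1), 2L),
    phrase = tolower(vapply(parts, `[`, character(1), 3L)),
    whole_line = nchar(vapply(parts, `[`, character(1), 3L)) <= 3L,
    stringsAsFactors = FALSE
  )
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Locate header phrases at line starts. Returns a data frame of matches with
# absolute 0-based offsets (phrase start; header end includes an optional
# trailing colon). Longest phrase wins at a given position.
find_headers <- function(text, keywords) {
  # absolute 0-based offset of each line start
  line_starts <- c(0L, gregexpr("\n", text, fixed = TRUE)[[1L]])
  if (line_starts[2L] == -1L && length(line_starts) == 2L) {
    line_starts <- 0L
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(lines) == 0L) lines <- ""
  # order phrases longest-first so alternation prefers the longest header
  kw <- keywords[order(-nchar(keywords$phrase)), , drop = FALSE]
  out <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    low <- tolower(line)
    for (j in seq_len(nrow(kw))) {
      phrase <- kw$phrase[j]
      pat <- if (kw$whole_line[j]) {
        sprintf("^(\\s*)(%s)(\\s*:)?\\s*$", regex_escape(phrase))
      } else {
        sprintf("^(\\s*)(%s)(\\s*:)?", regex_escape(phrase))
      }
      m <- regexec(pat, low, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      # group 1 = leading whitespace, group 2 = phrase, group 3 = colon part
      g_start <- m[3L] - 1L   # 0-based within line, phrase start
      g_len <- attr(m, "match.length")[3L]
      colon_len <- attr(m, "match.length")[4L]
      if (is.na(colon_len) || colon_len < 0L) colon_len <- 0L
      hs <- line_starts[i] + g_start
      out[[length(out) + 1L]] <- data.frame(
        label = kw$label[j],
        header_start = hs,
        header_end = hs + g_len + colon_len,
        stringsAsFactors = FALSE
      )
      break  # one header per line; longest phrase taken first
    }
  }
  if (length(out) == 0L) {
    return(data.frame(label = character(0), header_start = integer(0),
                      header_end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Tag history sections of a note
#'
#' Splits a note into labeled sections by matching header keywords
#' (case-insensitively) at line starts. Each section body extends from the
#' end of its header to the start of the next recognized header, or the end
#' of the text. Text before the first header forms a single `other` section
#' with a zero-width header span. The returned sections are non-overlapping,
#' ordered by offset, and partition the text: concatenating header and body
#' spans over all sections reconstructs the document exactly.
#'
#' @param text Note text.
#' @param keywords Keyword table (see [default_section_keywords()]).
#' @return Data frame with columns `label`, `header_start`, `header_end`,
#'   `body_start`, `body_end` (0-based half-open offsets). Empty text yields
#'   zero rows.
#' @export
#' @examples
#' tag_sections("FAMILY HISTORY\nnotable for CAD")
tag_sections <- function(text, keywords = default_section_keywords()) {
  empty <- data.frame(label = character(0), header_start = integer(0),
                      header_end = integer(0), body_start = integer(0),
                      body_end = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  h <- find_headers(text, keywords)
  n <- nchar(text)
  if (nrow(h) == 0L) {
    return(data.frame(label = "other", header_start = 0L, header_end = 0L,
                      body_start = 0L, body_end = n,
                      stringsAsFactors = FALSE))
  }
  h <- h[order(h$header_start), , drop = FALSE]
  secs <- h
  secs$body_start <- secs$header_end
  secs$body_end <- c(secs$header_start[-1L], n)
  if (secs$header_start[1L] > 0L) {
    lead <- data.frame(label = "other", header_start = 0L, header_end = 0L,
                       body_start = 0L, body_end = secs$header_start[1L],
                       stringsAsFactors = FALSE)
    secs <- rbind(lead, secs)
  }
  rownames(secs) <- NULL
  secs[, c("label", "header_start", "header_end", "body_start", "body_end")]
}

# Ensure a document has its sections tagged.
with_sections <- function(doc, keywords = default_section_keywords()) {
  if (is.null(doc$sections)) doc$sections <- tag_sections(doc$text, keywords)
  doc
}

#' History sections of a document
#'
#' The labeled (non-`other`) sections of a note, in document order. These
#' are the sections with a higher likelihood of containing age- and
#' temporally-specified clinical events, and the only sections the
#' recognizers operate on.
#'
#' @param doc A `clinhist_document`, or a section table from
#'   [tag_sections()].
#' @return Section data frame with `label != "other"`.
#' @export
history_sections <- function(doc) {
  secs <- if (inherits(doc, "clinhist_document")) {
    with_sections(doc)$sections
  } else {
    doc
  }
  out <- secs[secs$label != "other", , drop = FALSE]
  rownames(out) <- NULL
  out
}
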