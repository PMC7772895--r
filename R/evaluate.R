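# Overlapping-span NER scoring and three-level agreement: level 1 matches
# on span overlap + class, level 2 additionally requires equal attributes
# (and concept code), level 3 additionally requires the matched entities'
# relationships to correspond under the pairing.

attrs_equal <- function(a, b) {
  na <- sort(names(a)); nb <- sort(names(b))
  if (!identical(na, nb)) return(FALSE)
  all(vapply(na, function(k) {
    identical(as.character(a[[k]]), as.character(b[[k]]))
  }, logical(1)))
}

code_equal <- function(a, b) {
  (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && identical(a, b))
}

# Incident relationships of entity id, as "type|role|partner" keys with the
# partner id mapped through `map` (NA when the partner is unmapped).
incident_rels <- function(rels, id, map = NULL) {
  if (nrow(rels) == 0L) return(character(0))
  inc <- rels[rels$source == id | rels$target == id, , drop = FALSE]
  if (nrow(inc) == 0L) return(character(0))
  role <- ifelse(inc$source == id, "src", "tgt")
  partner <- ifelse(inc$source == id, inc$target, inc$source)
  if (!is.null(map)) partner <- unname(map[partner])
  sort(paste(inc$type, role, ifelse(is.na(partner), "<unmapped>", partner),
             sep = "|"))
}

#' Match gold and system entities by overlapping spans
#'
#' Pairs entities one-to-one when their spans share at least one character
#' and their classes agree, greedily by decreasing overlap length and then
#' by gold start offset (then system start, for determinism). At level 2 a
#' paired entity counts as a true positive only if all attributes and the
#' concept code agree; at level 3 its incident relationships must in
#' addition correspond exactly under the pairing (no partial credit).
#' Paired entities failing the stricter criteria are demoted to one false
#' positive plus one false negative, so match counts nest across levels by
#' construction. Unmatched system entities are false positives, unmatched
#' gold entities false negatives.
#'
#' @param gold,system Entity data frames over the same document text.
#' @param level Strictness level 1, 2, or 3.
#' @param gold_rels,system_rels Relationship tables (required meaningfully
#'   at level 3; default empty).
#' @return List with `counts` (per-class data frame: `class`, `tp`, `fp`,
#'   `fn`) and `pairing` (data frame `gold_id`, `system_id`, `overlap`,
#'   `matched` flag at the requested level).
#' @export
match_entities <- function(gold, system, level = 1L,
                           gold_rels = empty_relationships(),
                           system_rels = empty_relationships()) {
  stopifnot(level %in% 1:3)
  pairs <- list()
  for (i in seq_len(nrow(gold))) {
    for (j in seq_len(nrow(system))) {
      if (gold$class[i] != system$class[j]) next
      ov <- min(gold$end[i], system$end[j]) -
        max(gold$start[i], system$start[j])
      if (ov <= 0L) next
      pairs[[length(pairs) + 1L]] <- c(i, j, ov)
    }
  }
  pairing <- data.frame(gold_id = character(0), system_id = character(0),
                        overlap = integer(0), matched = logical(0),
                        stringsAsFactors = FALSE)
  gi_used <- logical(nrow(gold)); sj_used <- logical(nrow(system))
  if (length(pairs) > 0L) {
    pm <- do.call(rbind, pairs)
    ord <- order(-pm[, 3L], gold$start[pm[, 1L]], system$start[pm[, 2L]])
    pm <- pm[ord, , drop = FALSE]
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, 1L]; j <- pm[r, 2L]
      if (gi_used[i] || sj_used[j]) next
      gi_used[i] <- TRUE; sj_used[j] <- TRUE
      pairing <- rbind(pairing, data.frame(
        gold_id = gold$id[i], system_id = system$id[j],
        overlap = pm[r, 3L], matched = TRUE, stringsAsFactors = FALSE))
    }
  }
  if (level >= 2L && nrow(pairing) > 0L) {
    for (r in seq_len(nrow(pairing))) {
      i <- match(pairing$gold_id[r], gold$id)
      j <- match(pairing$system_id[r], system$id)
      ok <- attrs_equal(gold$attrs[[i]], system$attrs[[j]]) &&
        code_equal(gold$associated_code[i], system$associated_code[j])
      pairing$matched[r] <- ok
    }
  }
  if (level >= 3L && nrow(pairing) > 0L) {
    map <- stats::setNames(pairing$system_id, pairing$gold_id)
    for (r in seq_len(nrow(pairing))) {
      if (!pairing$matched[r]) next
      want <- incident_rels(gold_rels, pairing$gold_id[r], map)
      got <- incident_rels(system_rels, pairing$system_id[r])
      pairing$matched[r] <- identical(want, got)
    }
  }
  classes <- sort(unique(c(gold$class, system$class)))
  counts <- do.call(rbind, lapply(classes, function(cl) {
    gids <- gold$id[gold$class == cl]
    sids <- system$id[system$class == cl]
    ok <- pairing$matched & pairing$gold_id %in% gids
    tp <- sum(ok)
    data.frame(class = cl, tp = tp,
               fp = length(sids) - tp, fn = length(gids) - tp,
               stringsAsFactors = FALSE)
  }))
  if (is.null(counts)) {
    counts <- data.frame(class = character(0), tp = integer(0),
                         fp = integer(0), fn = integer(0),
                         stringsAsFactors = FALSE)
  }
  list(counts = counts, pairing = pairing)
}

#' Precision, recall, and F1 from match counts
#'
#' `P = tp / (tp + fp)`, `R = tp / (tp + fn)`, `F1 = 2PR / (P + R)`; each is
#' 0 by convention when its denominator is 0.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return Data frame with columns `precision`, `recall`, `f1`.
#' @export
#' @examples
#' score_counts(2, 1, 1)  # P = R = F1 = 2/3
score_counts <- function(tp, fp, fn) {
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  data.frame(precision = p, recall = r, f1 = f)
}

sum_counts <- function(counts_list) {
  all <- do.call(rbind, counts_list)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(class = character(0), tp = integer(0),
                      fp = integer(0), fn = integer(0),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(cbind(tp, fp, fn) ~ class, data = all, FUN = sum)
  agg[order(agg$class), , drop = FALSE]
}

report_from_counts <- function(counts, level) {
  overall <- data.frame(class = "overall", tp = sum(counts$tp),
                        fp = sum(counts$fp), fn = sum(counts$fn),
                        stringsAsFactors = FALSE)
  out <- rbind(counts, overall)
  out <- cbind(out, score_counts(out$tp, out$fp, out$fn))
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("clinhist_eval", class(out))
  out
}

#' @export
print.clinhist_eval <- function(x, ...) {
  cat(sprintf("<clinhist_eval> level %d (overlapping spans%s)\n",
              attr(x, "level"),
              c("", " + attributes", " + attributes + relationships")[
                attr(x, "level")]))
  df <- as.data.frame(x)
  df$precision <- sprintf("%.3f", df$precision)
  df$recall <- sprintf("%.3f", df$recall)
  df$f1 <- sprintf("%.3f", df$f1)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Score a system document against a gold document
#'
#' Runs [match_entities()] at the requested strictness level and reports
#' per-class and overall precision, recall, and F1.
#'
#' @param gold,system `clinhist_document`s over the same text, or corpora
#'   ([new_corpus()]) over the same document set (counts are then summed
#'   across documents before scoring).
#' @param level Strictness level 1, 2, or 3.
#' @param classes Optional class subset to evaluate (entities of other
#'   classes are dropped from both sides first).
#' @return A `clinhist_eval` data frame with per-class rows plus an
#'   `overall` row.
#' @export
evaluate_ner <- function(gold, system, level = 1L, classes = NULL) {
  pick <- function(ents) {
    if (is.null(classes)) ents else
      ents[ents$class %in% classes, , drop = FALSE]
  }
  if (inherits(gold, "clinhist_corpus")) {
    stopifnot(inherits(system, "clinhist_corpus"),
              setequal(names(gold$documents), names(system$documents)))
    counts <- lapply(names(gold$documents), function(id) {
      g <- gold$documents[[id]]; s <- system$documents[[id]]
      match_entities(pick(g$entities), pick(s$entities), level,
                     g$relationships, s$relationships)$counts
    })
    return(report_from_counts(sum_counts(counts), level))
  }
  stopifnot(inherits(gold, "clinhist_document"),
            inherits(system, "clinhist_document"))
  if (!identical(gold$text, system$text)) {
    stop("gold and system annotations reference different document texts")
  }
  m <- match_entities(pick(gold$entities), pick(system$entities), level,
                      gold$relationships, system$relationships)
  report_from_counts(m$counts, level)
}

#' Inter-annotator agreement report
#'
#' F1 agreement of each annotator against a reference standard at the three
#' strictness levels (named entities; + attributes; + attributes +
#' relationships), per class and overall.
#'
#' @param annotators Named list of `clinhist_corpus` objects, one per
#'   annotator, over the same documents as `reference`.
#' @param reference Reference-standard `clinhist_corpus`.
#' @return Data frame with columns `annotator`, `level`, `class`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
iaa_report <- function(annotators, reference) {
  stopifnot(is.list(annotators), length(names(annotators)) ==
              length(annotators))
  out <- list()
  for (nm in names(annotators)) {
    ann <- annotators[[nm]]
    stopifnot(setequal(names(ann$documents), names(reference$documents)))
    for (lv in 1:3) {
      rep <- evaluate_ner(reference, ann, level = lv)
      rep <- as.data.frame(rep)
      rep <- cbind(data.frame(annotator = nm, level = lv,
                              stringsAsFactors = FALSE), rep)
      out[[length(out) + 1L]] <- rep
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
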