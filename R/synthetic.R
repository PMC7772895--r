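# Seeded generator of fictitious, Safe-Harbor-style clinical notes with
# gold standoff annotations. Documents are assembled from sentence
# templates whose slots (kin terms, disorders and procedures from the demo
# lexicon, ages, years) are sampled; every planted slot is recorded as a
# gold entity with exact offsets, attributes, and relationships. All names
# and places are fictitious by construction; no real identifiers can be
# emitted.

#' Generator configuration
#'
#' Defaults encode the corpus conditions the generator emulates: per-class
#' mean mentions per document matching the reference corpus marginals
#' (TIMEX3 1.27, AGE 1.08, SUBJECT_CLASS 0.67, DISEASE_DISORDER 6.25,
#' PROCEDURE 1.46, OTHER_EVENTS 3.25), the social-determinant type mixture
#' (substance use 87, living situation 26, occupation 20, martial status 8,
#' death 6, exposure 3, other 5, normalized), and a predominantly
#' fully-specified age-type mixture (0.94/0.03/0.03). Per-document entity
#' counts are drawn as `floor(rate) + Bernoulli(fractional part)`, so
#' empirical corpus rates converge tightly to the configured rates.
#'
#' @param n_documents Number of documents to generate.
#' @param seed Integer seed fixing all randomness.
#' @param rates Named mean mentions/document per entity class.
#' @param oe_mixture Named OTHER_EVENTS type mixture (normalized to sum 1).
#' @param age_type_mixture Named AGE type mixture (fully/less/event).
#' @param section_probs Inclusion probability per history section; a
#'   section is additionally forced in whenever the sampled content needs
#'   it.
#' @param p_relationship Probability that a template's canonical
#'   relationships are planted for a sentence.
#' @param p_distractor Probability of planting a numeric distractor line
#'   (medication dose, pack-year exposure) in a document, exercising the
#'   false-positive modes of naive temporal patterns.
#' @return List of class `clinhist_generator_config`.
#' @export
generator_config <- function(n_documents = 110L, seed = 1L,
                             rates = c(TIMEX3 = 1.27, AGE = 1.08,
                                       SUBJECT_CLASS = 0.67,
                                       DISEASE_DISORDER = 6.25,
                                       PROCEDURE = 1.46,
                                       OTHER_EVENTS = 3.25),
                             oe_mixture = c("substance use" = 87,
                                            "living situation" = 26,
                                            "occupation" = 20,
                                            "martial status" = 8,
                                            "death" = 6, "exposure" = 3,
                                            "other" = 5),
                             age_type_mixture = c("fully-specified" = 0.94,
                                                  "less-specified" = 0.03,
                                                  "event-specified" = 0.03),
                             section_probs = c(past_medical_history = 0.95,
                                               past_surgical_history = 0.6,
                                               family_history = 0.75,
                                               social_history = 0.85),
                             p_relationship = 1,
                             p_distractor = 0.5) {
  stopifnot(n_documents >= 1L, all(rates >= 0),
            setequal(names(rates), unname(entity_classes())),
            all(oe_mixture >= 0), sum(oe_mixture) > 0,
            all(age_type_mixture >= 0), sum(age_type_mixture) > 0)
  if (sum(rates) > 50) {
    stop("configured rates imply more than 50 entities per document, ",
         "beyond template capacity")
  }
  structure(list(
    n_documents = as.integer(n_documents), seed = as.integer(seed),
    rates = rates,
    oe_mixture = oe_mixture / sum(oe_mixture),
    age_type_mixture = age_type_mixture / sum(age_type_mixture),
    section_probs = section_probs,
    p_relationship = p_relationship,
    p_distractor = p_distractor
  ), class = "clinhist_generator_config")
}

# --- document builder: a sentence is a list of pieces; an entity piece
# carries class/attrs/code, a plain piece only text. -------------------

piece <- function(text, class = NULL, attrs = list(),
                  code = NA_character_) {
  list(text = text, class = class, attrs = attrs, code = code)
}

# relationships: list of c(from_piece, to_piece) indices within a sentence
sentence <- function(pieces, rels = list()) {
  list(pieces = pieces, rels = rels)
}

# sample helpers -------------------------------------------------------

sample1 <- function(x) x[sample.int(length(x), 1L)]

sample_mix <- function(n, mixture) {
  if (n == 0L) return(character(0))
  sample(names(mixture), n, replace = TRUE, prob = mixture)
}

count_from_rate <- function(rate) {
  k <- floor(rate) + stats::rbinom(1L, 1L, rate - floor(rate))
  min(as.integer(k), 50L)
}

generator_lexicon_terms <- function() {
  lx <- demo_lexicon()$entries
  map <- default_semantic_map()
  dd <- lx[lx$semantic_type %in% map$DISEASE_DISORDER, , drop = FALSE]
  p <- lx[lx$semantic_type %in% map$PROCEDURE, , drop = FALSE]
  list(dd = dd, p = p)
}

kin_terms_for_generation <- function() {
  c("father", "mother", "sister", "brother", "aunt", "uncle",
    "grandmother", "grandfather", "son", "daughter", "cousin",
    "maternal uncle", "paternal aunt", "maternal grandmother")
}

subject_piece <- function(term, implicit = FALSE) {
  lex <- subject_lexicon()
  base <- sub("^(maternal|paternal)\\s+", "", tolower(term))
  norm <- lex$normalization[match(base, lex$term)]
  if (is.na(norm)) norm <- "family_member"
  piece(term, "SUBJECT_CLASS",
        attrs = list(normalization = norm,
                     degree_relation = degree_relation(term),
                     implicit = if (implicit) "true" else "false"))
}

dd_piece <- function(row, section = "past_medical_history") {
  piece(row$term, "DISEASE_DISORDER",
        attrs = list(doctimerel = default_doctimerel("DISEASE_DISORDER",
                                                     section)),
        code = row$concept_id)
}

p_piece <- function(row, section = "past_surgical_history") {
  piece(row$term, "PROCEDURE",
        attrs = list(doctimerel = default_doctimerel("PROCEDURE", section)),
        code = row$concept_id)
}

age_piece <- function(type) {
  if (type == "fully-specified") {
    n <- sample(25:90, 1L)
    form <- sample1(c("age", "yo", "yearold"))
    txt <- switch(form,
                  age = sprintf("age %d", n),
                  yo = sprintf("%dyo", n),
                  yearold = sprintf("%d-year-old", n))
    return(piece(txt, "AGE", attrs = list(type = "fully-specified")))
  }
  if (type == "less-specified") {
    return(piece(sprintf("%d0s", sample(4:8, 1L)), "AGE",
                 attrs = list(type = "less-specified")))
  }
  piece(sample1(c("childhood", "adolescence", "infancy")), "AGE",
        attrs = list(type = "event-specified"))
}

year_piece <- function() {
  piece(sprintf("%d", sample(1975:2013, 1L)), "TIMEX3",
        attrs = list(type = "date"))
}

timex_piece <- function(kind = c("year", "iso", "ago", "duration")) {
  kind <- match.arg(kind)
  switch(kind,
    year = year_piece(),
    iso = piece(sprintf("%d-%02d-%02d", sample(1995:2013, 1L),
                        sample(1:12, 1L), sample(1:28, 1L)),
                "TIMEX3", attrs = list(type = "date")),
    ago = piece(sprintf("%d years ago", sample(2:20, 1L)),
                "TIMEX3", attrs = list(type = "date")),
    duration = piece(sprintf("for %d years", sample(5:30, 1L)),
                     "TIMEX3", attrs = list(type = "duration"))
  )
}

# --- sentence factories; each returns a sentence() whose entity pieces
# consume the caller's budgets. ----------------------------------------

kin_sentence <- function(kin, dd_row, age, death) {
  pieces <- list()
  rels <- list()
  s_i <- NA_integer_; oe_i <- NA_integer_; dd_i <- NA_integer_
  a_i <- NA_integer_
  add <- function(p) {
    pieces[[length(pieces) + 1L]] <<- p
    length(pieces)
  }
  kin_cap <- paste0(toupper(substr(kin, 1, 1)), substr(kin, 2, nchar(kin)))
  if (!is.null(age) && identical(age$attrs$type, "fully-specified") &&
      grepl("yo$|year-old$", age$text) && is.null(death)) {
    # "61yo mother has HTN."
    a_i <- add(age); add(piece(" "))
    s_i <- add(subject_piece(kin)); add(piece(" has "))
    if (!is.null(dd_row)) {
      dd_i <- add(dd_piece(dd_row, "family_history")); add(piece("."))
    } else {
      add(piece("a history of illness."))
    }
  } else if (!is.null(death)) {
    # "Father died of MI at age 69."
    s_i <- add(subject_piece(kin_cap))
    add(piece(" "))
    oe_i <- add(piece("died", "OTHER_EVENTS",
                      attrs = list(type = "death",
                                   doctimerel = "before")))
    if (!is.null(dd_row)) {
      add(piece(" of "))
      dd_i <- add(dd_piece(dd_row, "family_history"))
    }
    if (!is.null(age)) {
      if (identical(age$attrs$type, "less-specified")) {
        add(piece(" in her "))
      } else {
        add(piece(" at "))
        if (!grepl("^age", age$text)) age$text <- paste("age",
          regmatches(age$text, regexpr("\\d+", age$text)))
      }
      a_i <- add(age)
    }
    add(piece("."))
  } else {
    # "Mother had breast cancer in her 50s." / "Sister has asthma."
    s_i <- add(subject_piece(kin_cap))
    tense <- sample1(c(" has ", " had "))
    if (!is.null(dd_row)) {
      add(piece(tense))
      dd_i <- add(dd_piece(dd_row, "family_history"))
    } else {
      add(piece(" is in good health"))
    }
    if (!is.null(age)) {
      if (identical(age$attrs$type, "less-specified")) {
        add(piece(" in his "))
        a_i <- add(age)
      } else {
        add(piece(" at "))
        if (!grepl("^age", age$text)) age$text <- paste("age",
          regmatches(age$text, regexpr("\\d+", age$text)))
        a_i <- add(age)
      }
    }
    add(piece("."))
  }
  if (!is.na(oe_i) && !is.na(s_i)) rels <- c(rels, list(c(oe_i, s_i)))
  if (!is.na(dd_i) && !is.na(s_i)) rels <- c(rels, list(c(dd_i, s_i)))
  if (!is.na(oe_i) && !is.na(a_i)) rels <- c(rels, list(c(oe_i, a_i)))
  if (is.na(oe_i) && !is.na(dd_i) && !is.na(a_i)) {
    rels <- c(rels, list(c(dd_i, a_i)))
  }
  sentence(pieces, rels)
}

pmh_dd_sentence <- function(dd_row, timex = NULL, age = NULL) {
  pieces <- list(); rels <- list()
  add <- function(p) { pieces[[length(pieces) + 1L]] <<- p; length(pieces) }
  if (!is.null(age) && identical(age$attrs$type, "event-specified")) {
    add(piece("Patient had "))
    a_i <- add(age)
    add(piece(" "))
    dd_i <- add(dd_piece(dd_row, "past_medical_history"))
    add(piece("."))
    rels <- list(c(dd_i, a_i))
  } else if (!is.null(age)) {
    add(piece("Diagnosed with "))
    dd_i <- add(dd_piece(dd_row, "past_medical_history"))
    if (identical(age$attrs$type, "less-specified")) {
      add(piece(" in his "))
    } else {
      add(piece(" at "))
      if (!grepl("^age", age$text)) age$text <- paste("age",
        regmatches(age$text, regexpr("\\d+", age$text)))
    }
    a_i <- add(age)
    add(piece("."))
    rels <- list(c(dd_i, a_i))
  } else if (!is.null(timex)) {
    dd_i <- add(dd_piece(dd_row, "past_medical_history"))
    add(piece(" diagnosed in "))
    t_i <- add(timex)
    add(piece("."))
    rels <- list(c(dd_i, t_i))
  } else {
    add(dd_piece(dd_row, "past_medical_history"))
    add(piece("."))
  }
  sentence(pieces, rels)
}

psh_sentence <- function(p_row, timex = NULL) {
  pieces <- list(); rels <- list()
  add <- function(p) { pieces[[length(pieces) + 1L]] <<- p; length(pieces) }
  add(piece("s/p "))
  p_i <- add(p_piece(p_row))
  if (!is.null(timex)) {
    add(piece(" "))
    t_i <- add(timex)
    rels <- list(c(p_i, t_i))
  }
  add(piece("."))
  sentence(pieces, rels)
}

oe_sentence <- function(type, take_timex = NULL) {
  pieces <- list(); rels <- list()
  add <- function(p) { pieces[[length(pieces) + 1L]] <<- p; length(pieces) }
  oe <- function(txt, doctimerel = "before_overlap", negated = NULL,
                 code = NA_character_) {
    at <- list(type = type, doctimerel = doctimerel)
    if (!is.null(negated)) at$negated <- negated
    piece(txt, "OTHER_EVENTS", attrs = at, code = code)
  }
  if (type == "substance use") {
    v <- sample1(c("ex", "current", "never", "alcohol"))
    if (v == "ex") {
      oe_i <- add(oe("Ex-smoker", doctimerel = "before",
                     code = "C0028043"))
      timex <- if (is.null(take_timex)) NULL else take_timex("ago")
      if (!is.null(timex)) {
        add(piece(", quit "))
        t_i <- add(timex)
        rels <- list(c(oe_i, t_i))
      }
      add(piece("."))
    } else if (v == "current") {
      add(piece("Patient is a "))
      oe_i <- add(oe("current everyday smoker", code = "C0028043"))
      timex <- if (is.null(take_timex)) NULL else take_timex("duration")
      if (!is.null(timex)) {
        add(piece(", smoking "))
        t_i <- add(timex)
        rels <- list(c(oe_i, t_i))
      }
      add(piece("."))
    } else if (v == "never") {
      add(piece("Denies "))
      add(oe("tobacco use", doctimerel = "unknown", negated = "true",
             code = "C0028043"))
      add(piece("."))
    } else {
      oe_i <- add(oe("Drinks one glass of wine daily",
                     code = "C0001973"))
      add(piece("."))
    }
  } else if (type == "living situation") {
    add(oe(sample1(c("Lives alone", "Lives in a nursing home",
                     "Lives at home with support"))))
    add(piece("."))
  } else if (type == "occupation") {
    v <- sample1(c("factory", "nurse", "retired"))
    if (v == "factory") {
      add(piece("Patient is a "))
      add(oe("factory worker"))
      add(piece("."))
    } else if (v == "nurse") {
      add(oe("Works as a nurse"))
      add(piece("."))
    } else {
      add(oe("Retired schoolteacher", doctimerel = "before"))
      add(piece("."))
    }
  } else if (type == "martial status") {
    add(oe(sample1(c("Married", "Divorced", "Widowed"))))
    add(piece("."))
  } else if (type == "exposure") {
    add(oe("Exposed to asbestos at work", doctimerel = "before"))
    add(piece("."))
  } else if (type == "good health") {
    add(oe("In good health"))
    add(piece("."))
  } else {
    add(oe(sample1(c("Does not speak English",
                     "Uses a walker at baseline")),
           doctimerel = "before_overlap"))
    add(piece("."))
  }
  sentence(pieces, rels)
}

distractor_lines <- function() {
  c("Lisinopril 10 mg daily.", "Metoprolol 25 mg twice daily.",
    "45 pack-year smoking history.", "Oxygen 2 L by nasal cannula.")
}

# Linearize sections of sentences into text + gold entities/relationships.
assemble_document <- function(doc_id, creation_date, section_sentences,
                              p_relationship) {
  text <- "Discharge summary.\n\n"
  headers <- c(past_medical_history = "Past Medical History:",
               past_surgical_history = "Past Surgical History:",
               family_history = "Family History:",
               social_history = "Social History:")
  ents <- list()
  rels <- list()
  k <- 0L
  for (sec in names(headers)) {
    sentences <- section_sentences[[sec]]
    if (is.null(sentences)) next
    header <- headers[[sec]]
    if (sec == "family_history") {
      # the "family" token of the header is an implicit subject mention
      fam_start <- nchar(text)
      k <- k + 1L
      ents[[k]] <- new_entity(sprintf("E%d", k), "SUBJECT_CLASS",
                              fam_start, fam_start + 6L, "Family",
                              attrs = list(normalization = "family_member",
                                           degree_relation = "unknown",
                                           implicit = "true"))
    }
    text <- paste0(text, header, "\n")
    for (s in sentences) {
      ids <- rep(NA_character_, length(s$pieces))
      for (pi in seq_along(s$pieces)) {
        p <- s$pieces[[pi]]
        start <- nchar(text)
        text <- paste0(text, p$text)
        if (!is.null(p$class)) {
          k <- k + 1L
          ids[pi] <- sprintf("E%d", k)
          ents[[k]] <- new_entity(ids[pi], p$class, start,
                                  start + nchar(p$text), p$text,
                                  attrs = p$attrs,
                                  associated_code = p$code)
        }
      }
      text <- paste0(text, "\n")
      if (length(s$rels) > 0L && stats::runif(1L) <= p_relationship) {
        for (r in s$rels) {
          src <- ids[r[1L]]; tgt <- ids[r[2L]]
          src_cls <- s$pieces[[r[1L]]]$class
          tgt_cls <- s$pieces[[r[2L]]]$class
          rels[[length(rels) + 1L]] <- new_relationship(
            src, tgt, sprintf("%s-to-%s", class_tag(src_cls),
                              class_tag(tgt_cls)))
        }
      }
    }
  }
  relationships <- if (length(rels) == 0L) empty_relationships() else
    do.call(rbind, rels)
  new_document(doc_id, text, creation_date = creation_date,
               entities = bind_entities(ents),
               relationships = relationships)
}

generate_document <- function(cfg, idx, lex_terms) {
  rates <- cfg$rates
  k <- vapply(unname(entity_classes()), function(cl)
    count_from_rate(rates[[cl]]), integer(1))
  names(k) <- unname(entity_classes())
  creation_date <- as.Date("2013-01-01") + sample(0:1095, 1L)

  present <- stats::runif(length(cfg$section_probs)) < cfg$section_probs
  names(present) <- names(cfg$section_probs)

  n_s <- k[["SUBJECT_CLASS"]]
  n_a <- k[["AGE"]]; n_t <- k[["TIMEX3"]]
  n_dd <- k[["DISEASE_DISORDER"]]; n_p <- k[["PROCEDURE"]]
  n_oe <- k[["OTHER_EVENTS"]]

  oe_types <- sample_mix(n_oe, cfg$oe_mixture)
  age_types <- sample_mix(n_a, cfg$age_type_mixture)
  # decades and life stages need specific sentence contexts; keep at most
  # one of each per document and draw the rest fully-specified
  age_types[duplicated(age_types) & age_types != "fully-specified"] <-
    "fully-specified"

  secs <- list(past_medical_history = list(),
               past_surgical_history = list(),
               family_history = list(), social_history = list())
  push <- function(sec, s) secs[[sec]][[length(secs[[sec]]) + 1L]] <<- s

  # family history: first subject is the implicit header mention
  n_kin <- if (n_s > 0L) n_s - 1L else 0L
  n_death <- sum(oe_types == "death")
  if (n_death > n_kin) {
    oe_types[which(oe_types == "death")[seq_len(n_death - n_kin)]] <- "other"
    n_death <- n_kin
  }
  deaths_left <- n_death
  ages_left <- age_types
  take_age <- function(context) {
    # context "kin"/"pmh": decades need possessive context (both ok),
    # life stages only fit the medical-history template
    if (length(ages_left) == 0L) return(NULL)
    pick <- if (context == "kin") {
      which(ages_left != "event-specified")[1L]
    } else {
      seq_along(ages_left)[1L]
    }
    if (is.na(pick)) return(NULL)
    type <- ages_left[pick]
    ages_left <<- ages_left[-pick]
    age_piece(type)
  }
  dd_left <- n_dd
  take_dd <- function() {
    if (dd_left == 0L) return(NULL)
    dd_left <<- dd_left - 1L
    lex_terms$dd[sample.int(nrow(lex_terms$dd), 1L), , drop = FALSE]
  }
  t_left <- n_t
  take_timex <- function(kind) {
    if (t_left == 0L) return(NULL)
    t_left <<- t_left - 1L
    timex_piece(kind)
  }

  if (n_s > 0L) {
    for (i in seq_len(n_kin)) {
      kin <- sample1(kin_terms_for_generation())
      death <- if (deaths_left > 0L) { deaths_left <- deaths_left - 1L; TRUE
        } else NULL
      push("family_history",
           kin_sentence(kin, take_dd(), take_age("kin"), death))
    }
  }

  # procedures with optional year
  if (n_p > 0L) {
    for (i in seq_len(n_p)) {
      row <- lex_terms$p[sample.int(nrow(lex_terms$p), 1L), , drop = FALSE]
      push("past_surgical_history", psh_sentence(row, take_timex("year")))
    }
  }

  # social determinants; smoking sentences may consume a time expression
  oe_social <- oe_types[oe_types != "death"]
  provider <- function(kind) {
    if (t_left > 0L && stats::runif(1L) < 0.5) take_timex(kind) else NULL
  }
  for (type in oe_social) {
    push("social_history",
         oe_sentence(type, if (type == "substance use") provider))
  }

  # remaining ages and dates ride on medical-history sentences
  while (length(ages_left) > 0L && dd_left > 0L) {
    push("past_medical_history",
         pmh_dd_sentence(take_dd(), age = take_age("pmh")))
  }
  while (length(ages_left) > 0L) {
    age <- take_age("pmh")
    s <- if (identical(age$attrs$type, "event-specified")) {
      sentence(list(piece("Hospitalized in "), age, piece(".")))
    } else if (identical(age$attrs$type, "less-specified")) {
      sentence(list(piece("First symptoms in his "), age, piece(".")))
    } else {
      sentence(list(piece("Hospitalized at "),
                    local({
                      a <- age
                      if (!grepl("^age", a$text)) a$text <- paste("age",
                        regmatches(a$text, regexpr("\\d+", a$text)))
                      a
                    }), piece(".")))
    }
    push("past_medical_history", s)
  }
  while (t_left > 0L && dd_left > 0L) {
    push("past_medical_history",
         pmh_dd_sentence(take_dd(), timex = take_timex(
           sample1(c("year", "iso")))))
  }
  while (t_left > 0L) {
    tm <- take_timex(sample1(c("year", "iso")))
    push("past_medical_history",
         sentence(list(piece("Hospitalized in "), tm, piece("."))))
  }
  while (dd_left > 0L) {
    push("past_medical_history", pmh_dd_sentence(take_dd()))
  }

  # distractors exercise numeric false-positive modes
  if (stats::runif(1L) < cfg$p_distractor) {
    line <- sample1(distractor_lines())
    sec <- if (grepl("pack-year", line)) "social_history" else
      "past_medical_history"
    push(sec, sentence(list(piece(line))))
  }

  # the family-history section exists iff the document has subjects: the
  # header itself carries the implicit "Family" subject mention, so an
  # unplanned section would distort the subject rate
  if (n_s > 0L && length(secs$family_history) == 0L) {
    push("family_history", sentence(list(piece("Noncontributory."))))
  }
  # other sections drawn present but left empty get a neutral filler line
  for (sec in names(secs)) {
    if (sec == "family_history") next
    if (length(secs[[sec]]) == 0L && present[[sec]]) {
      push(sec, sentence(list(piece("Noncontributory."))))
    }
  }
  if (all(vapply(secs, length, integer(1)) == 0L)) {
    push("past_medical_history", sentence(list(piece("Noncontributory."))))
  }
  secs <- Filter(function(s) length(s) > 0L, secs)

  assemble_document(sprintf("doc%03d", idx), creation_date, secs,
                    cfg$p_relationship)
}

#' Generate a synthetic annotated corpus
#'
#' Produces `n_documents` fictitious discharge-summary-style notes, each
#' with a creation date, one to four history sections, and sentences drawn
#' from templates whose slots (kin terms, disorders and procedures from the
#' demo lexicon, ages, years) are sampled under the configured rates. Every
#' planted slot is recorded as a gold entity with exact offsets, class,
#' attributes (age type, TIMEX3 type, degree of relation, DocTimeRel,
#' social-determinant type), concept codes, and template relationships.
#' Regeneration with the same configuration is identical.
#'
#' @param config A [generator_config()].
#' @return A `clinhist_corpus` with gold annotations.
#' @export
#' @examples
#' corpus <- generate_corpus(generator_config(n_documents = 3, seed = 7))
#' corpus
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "clinhist_generator_config"))
  set.seed(config$seed)
  lex_terms <- generator_lexicon_terms()
  docs <- lapply(seq_len(config$n_documents), function(i) {
    generate_document(config, i, lex_terms)
  })
  new_corpus(docs)
}

#' Split a corpus into development/train/test/holdout sets
#'
#' Documents are shuffled under the seed and apportioned by the
#' largest-remainder method: each split receives the floor of its exact
#' quota, and leftover documents go to the splits with the largest
#' fractional remainders (ties broken by split order).
#'
#' @param corpus A `clinhist_corpus`.
#' @param ratios Positive ratios, default `15:45:20:20`.
#' @param seed Shuffle seed.
#' @return Named character vector: doc_id -> split label.
#' @export
#' @examples
#' corpus <- generate_corpus(generator_config(n_documents = 20, seed = 1))
#' table(split_corpus(corpus, seed = 1))
split_corpus <- function(corpus,
                         ratios = c(development = 15, train = 45,
                                    test = 20, holdout = 20),
                         seed = 1L) {
  stopifnot(all(ratios >= 0), sum(ratios > 0) >= 1L)
  n <- length(corpus$documents)
  if (n < sum(ratios > 0)) {
    stop("fewer documents than nonzero ratio groups")
  }
  quota <- n * ratios / sum(ratios)
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    frac_ord <- order(-(quota - sizes), seq_along(quota))
    bump <- frac_ord[seq_len(rem)]
    sizes[bump] <- sizes[bump] + 1L
  }
  set.seed(seed)
  ids <- sample(names(corpus$documents))
  labels <- rep(names(ratios), times = sizes)
  stats::setNames(labels, ids)[names(corpus$documents)]
}

#' Write a corpus to a directory
#'
#' Emits one `<doc_id>.txt` note (with a `DATE: YYYY-MM-DD` first-line
#' header when a creation date is present) and one `<doc_id>.json` standoff
#' file per document, plus a `manifest.tsv` listing documents and split
#' labels.
#'
#' @param corpus A `clinhist_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus$documents) {
    txt <- doc$text
    if (!is.null(doc$creation_date)) {
      txt <- paste0("DATE: ", format(doc$creation_date, "%Y-%m-%d"), "\n",
                    txt)
    }
    writeLines(txt, file.path(dir, paste0(doc$doc_id, ".txt")),
               sep = "", useBytes = TRUE)
    write_annotations(doc, file.path(dir, paste0(doc$doc_id, ".json")))
  }
  manifest <- data.frame(
    doc_id = names(corpus$documents),
    split = if (is.null(corpus$split_labels)) NA_character_ else
      unname(corpus$split_labels[names(corpus$documents)]),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' @param dir Directory containing `<doc_id>.json` standoff files and an
#'   optional `manifest.tsv` with split labels.
#' @return A `clinhist_corpus`.
#' @export
read_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  docs <- lapply(files, read_annotations)
  split_labels <- NULL
  mpath <- file.path(dir, "manifest.tsv")
  if (file.exists(mpath)) {
    m <- utils::read.delim(mpath, stringsAsFactors = FALSE)
    if (!all(is.na(m$split))) {
      split_labels <- stats::setNames(m$split, m$doc_id)
    }
  }
  new_corpus(docs, split_labels)
}
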