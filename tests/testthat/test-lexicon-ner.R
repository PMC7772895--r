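test_that("candidate windows enumerate token n-grams within lines", {
  w <- candidate_spans("one two three", max_tokens = 2L)
  expect_equal(nrow(w), 5L)  # 3 unigrams + 2 bigrams
  expect_equal(nrow(candidate_spans("", max_tokens = 3L)), 0L)
  # hyphenated compounds are single tokens
  w2 <- candidate_spans("end-stage renal disease", max_tokens = 6L)
  expect_true("end-stage renal disease" %in% w2$text)
  expect_true("end-stage" %in% w2$text)
  # windows neither start nor end on stopwords
  w3 <- candidate_spans("history of CAD", max_tokens = 3L)
  expect_false(any(grepl("^of | of$|^of$", w3$text)))
  # windows never span line breaks
  w4 <- candidate_spans("CAD\nHTN", max_tokens = 2L)
  expect_setequal(w4$text, c("CAD", "HTN"))
})

test_that("trigram similarity matches a brute-force enumeration", {
  expect_equal(trigram_similarity("appendectomy", "appendectomy"), 1)
  pairs <- list(c("hysterectom", "hysterectomy"),
                c("diabetes", "diabetes mellitus"),
                c("pneumonia", "pneumonie"),
                c("asthma", "arthritis"))
  for (p in pairs) {
    expect_equal(trigram_similarity(p[1], p[2]),
                 oracle_trigram_jaccard(p[1], p[2]))
  }
})

test_that("match_term returns the best entry above threshold", {
  lex <- demo_lexicon()
  hit <- match_term("appendectomy", lex)
  expect_identical(hit$entry$concept_id, "C0003611")
  expect_equal(hit$similarity, 1)
  # case/punctuation-insensitive exact matching
  expect_equal(match_term("Appendectomy", lex)$similarity, 1)
  # truncated surface matches iff its trigram Jaccard clears the threshold
  s <- oracle_trigram_jaccard("hysterectom", "hysterectomy")
  near <- match_term("hysterectom", lex, threshold = 0.8)
  if (s >= 0.8) {
    expect_identical(near$entry$concept_id, "C0020699")
    expect_equal(near$similarity, s)
  } else {
    expect_null(near)
  }
  expect_null(match_term("hysterectom", lex, threshold = 1.0))
  # acronyms resolve by exact synonym rows only
  expect_identical(match_term("CAD", lex)$entry$concept_id, "C0010054")
  expect_null(match_term("CAE", lex))
  # empty lexicon
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("concept_id\tterm\tsemantic_type\tis_preferred", p)
  expect_null(match_term("anything", read_lexicon(p)))
})

test_that("the dictionary matcher extracts coded disorder and procedure
          mentions from history sections", {
  txt <- paste0("Past Medical History:\n",
                "Patient with end-stage renal disease.\n",
                "Past Surgical History:\ns/p hysterectomy.\n")
  doc <- run_lexicon_ner(new_document("d", txt))
  dd <- doc$entities[doc$entities$class == "DISEASE_DISORDER", ]
  expect_identical(dd$text, "end-stage renal disease")
  expect_identical(dd$associated_code, "C2316810")
  expect_identical(dd$attrs[[1]]$doctimerel, "before_overlap")
  p <- doc$entities[doc$entities$class == "PROCEDURE", ]
  expect_identical(p$text, "hysterectomy")
  expect_identical(p$attrs[[1]]$doctimerel, "before")
  expect_identical(validate_document(doc), character(0))

  none <- run_lexicon_ner(new_document("d", "Social History:\nMarried.\n"))
  expect_equal(nrow(none$entities), 0L)
})

test_that("raising the threshold never increases the entity count", {
  corpus <- generate_corpus(generator_config(n_documents = 6, seed = 5))
  lex <- demo_lexicon()
  for (d in corpus$documents) {
    bare <- new_document(d$doc_id, d$text)
    counts <- vapply(c(0.5, 0.7, 0.8, 0.9, 1.0), function(th) {
      nrow(run_lexicon_ner(bare, lex, threshold = th)$entities)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("threshold 1.0 equals a naive exact dictionary scan", {
  lex <- demo_lexicon()
  map <- default_semantic_map()
  mapped <- lex
  mapped$entries <- lex$entries[lex$entries$semantic_type %in%
                                  unlist(map), , drop = FALSE]
  fixtures <- c(
    paste0("Past Medical History:\nCAD.\nend-stage renal disease.\n",
           "Past Surgical History:\ns/p appendectomy.\n"),
    paste0("Family History:\nmother with breast cancer.\n",
           "Social History:\nnothing relevant.\n"),
    paste0("Past Medical History:\ndiabetes mellitus.\nhypertension.\n",
           "atrial fibrillation.\n")
  )
  for (txt in fixtures) {
    doc <- run_lexicon_ner(new_document("d", txt), mapped, threshold = 1.0)
    got <- doc$entities[order(doc$entities$start), c("start", "end")]
    rownames(got) <- NULL
    want <- oracle_exact_scan(new_document("d", txt), mapped)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("semantic-type filtering adds and removes exactly its entities", {
  txt <- paste0("Past Medical History:\nCAD.\nbreast cancer.\n",
                "colonoscopy.\nprostate biopsy.\n",
                "Past Surgical History:\ns/p CABG.\n")
  doc <- new_document("d", txt)
  default <- run_lexicon_ner(doc, threshold = 1.0)
  # T060 diagnostic procedures are excluded by default
  expect_false(any(default$entities$text %in%
                     c("colonoscopy", "prostate biopsy")))
  with_t060 <- default_semantic_map()
  with_t060$PROCEDURE <- c(with_t060$PROCEDURE, "T060")
  more <- run_lexicon_ner(doc, threshold = 1.0, semantic_map = with_t060)
  added <- setdiff(more$entities$text, default$entities$text)
  expect_setequal(added, c("colonoscopy", "prostate biopsy"))
  # excluding a type removes exactly the entities carrying it
  no_t191 <- default_semantic_map()
  no_t191$DISEASE_DISORDER <- setdiff(no_t191$DISEASE_DISORDER, "T191")
  fewer <- run_lexicon_ner(doc, threshold = 1.0, semantic_map = no_t191)
  removed <- setdiff(default$entities$text, fewer$entities$text)
  expect_setequal(removed, "breast cancer")
})
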