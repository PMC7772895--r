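mk_ents <- function(...) bind_entities(...)

test_that("precision/recall/F1 arithmetic and degenerate conventions", {
  s <- score_counts(2, 1, 1)
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$recall, 2 / 3)
  expect_equal(s$f1, 2 / 3)
  z <- score_counts(0, 0, 0)
  expect_equal(unlist(z), c(precision = 0, recall = 0, f1 = 0))
  perfect <- score_counts(5, 0, 0)
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f1 = 1))
})

test_that("overlapping spans of the same class match at level 1", {
  gold <- new_entity("G1", "AGE", 10L, 16L, "age 69",
                     attrs = list(type = "fully-specified"))
  sys <- new_entity("S1", "AGE", 12L, 20L, "69 on adm",
                    attrs = list(type = "fully-specified"))
  m <- match_entities(gold, sys, level = 1)
  expect_equal(m$counts$tp, 1L)
  expect_equal(m$counts$fp + m$counts$fn, 0L)
  # no overlap, or different class: FP + FN
  far <- new_entity("S1", "AGE", 30L, 35L, "xxxxx")
  m2 <- match_entities(gold, far, level = 1)
  expect_equal(m2$counts$tp, 0L)
  other <- new_entity("S1", "TIMEX3", 10L, 16L, "age 69")
  m3 <- match_entities(gold, other, level = 1)
  expect_equal(sum(m3$counts$tp), 0L)
  expect_equal(sum(m3$counts$fp), 1L)
  expect_equal(sum(m3$counts$fn), 1L)
})

test_that("identical annotations score perfectly at every level", {
  d <- father_example_doc()
  for (lv in 1:3) {
    r <- evaluate_ner(d, d, level = lv)
    expect_true(all(r$f1 == 1))
  }
})

test_that("a differing concept code demotes a level-2 match to FP + FN", {
  gold <- new_entity("G1", "DISEASE_DISORDER", 0L, 23L,
                     "end-stage renal disease",
                     associated_code = "C2316810")
  sys <- new_entity("S1", "DISEASE_DISORDER", 0L, 23L,
                    "end-stage renal disease",
                    associated_code = "C0003611")
  l1 <- match_entities(gold, sys, level = 1)$counts
  expect_equal(l1$tp, 1L)
  l2 <- match_entities(gold, sys, level = 2)$counts
  expect_equal(l2$tp, 0L)
  expect_equal(l2$fp, 1L)
  expect_equal(l2$fn, 1L)
})

test_that("level-3 matches require relationships to map under the pairing", {
  d <- father_example_doc()
  # same entities but one relationship dropped on the system side
  sys <- d
  sys$relationships <- sys$relationships[-1, ]
  r3 <- evaluate_ner(d, sys, level = 3)
  r2 <- evaluate_ner(d, sys, level = 2)
  expect_true(all(r2$f1 == 1))
  # the two endpoints of the dropped relationship lose their credit
  expect_lt(r3$f1[r3$class == "overall"], 1)
})

test_that("F1 nests across strictness levels on perturbed corpora", {
  corpus <- generate_corpus(generator_config(n_documents = 5, seed = 21))
  set.seed(33)
  perturbed <- lapply(corpus$documents, function(d) {
    e <- d$entities
    # flip an attribute on ~20% of entities; drop a relationship sometimes
    for (i in seq_len(nrow(e))) {
      if (stats::runif(1) < 0.2 && length(e$attrs[[i]]) > 0) {
        a <- e$attrs[[i]]
        nm <- names(a)[1]
        vocab <- attribute_schema()[[e$class[i]]][[nm]]
        a[[nm]] <- sample(vocab, 1)
        e$attrs[[i]] <- a
      }
    }
    rels <- d$relationships
    if (nrow(rels) > 1 && stats::runif(1) < 0.5) rels <- rels[-1, ]
    new_document(d$doc_id, d$text, creation_date = d$creation_date,
                 entities = e, relationships = rels)
  })
  perturbed <- new_corpus(perturbed)
  f1 <- vapply(1:3, function(lv) {
    r <- evaluate_ner(corpus, perturbed, level = lv)
    r$f1[r$class == "overall"]
  }, numeric(1))
  expect_true(f1[3] <= f1[2] + 1e-12)
  expect_true(f1[2] <= f1[1] + 1e-12)
})

test_that("swapping gold and system swaps FP and FN at level 1", {
  corpus <- generate_corpus(generator_config(n_documents = 3, seed = 9))
  for (d in corpus$documents) {
    sys <- annotate_bare(d, threshold = 1.0)
    a <- evaluate_ner(d, sys, level = 1)
    b <- evaluate_ner(sys, d, level = 1)
    ov_a <- a[a$class == "overall", ]
    ov_b <- b[b$class == "overall", ]
    expect_equal(ov_a$tp, ov_b$tp)
    expect_equal(ov_a$fp, ov_b$fn)
    expect_equal(ov_a$fn, ov_b$fp)
  }
})

test_that("greedy pairing attains the exhaustive maximum on small sets", {
  # random fixtures: disjoint gold spans with boundary-jittered system
  # spans (the geometry NER outputs actually have)
  set.seed(77)
  for (trial in 1:30) {
    n_g <- sample(0:6, 1)
    starts <- cumsum(sample(8:12, max(n_g, 1), replace = TRUE))
    gold <- bind_entities(lapply(seq_len(n_g), function(i) {
      new_entity(paste0("G", i), sample(c("AGE", "TIMEX3"), 1),
                 starts[i], starts[i] + sample(2:5, 1), "x")
    }))
    sys <- bind_entities(lapply(seq_len(n_g), function(i) {
      if (stats::runif(1) < 0.2) return(NULL)  # dropped span
      j <- sample(-2:2, 1)
      new_entity(paste0("S", i), gold$class[i],
                 max(gold$start[i] + j, 0), gold$end[i] + sample(-1:2, 1),
                 "x")
    }))
    m <- match_entities(gold, sys, level = 1)
    expect_equal(sum(m$counts$tp), oracle_max_matching(gold, sys))
  }
  # multi-overlap fixtures resolved one-to-one
  gold <- bind_entities(new_entity("G1", "AGE", 0L, 10L, "x"),
                        new_entity("G2", "AGE", 20L, 30L, "x"))
  sys <- bind_entities(new_entity("S1", "AGE", 5L, 25L, "x"))
  m <- match_entities(gold, sys, level = 1)
  expect_equal(sum(m$counts$tp), 1L)
  expect_equal(sum(m$counts$tp), oracle_max_matching(gold, sys))
  sys2 <- bind_entities(new_entity("S1", "AGE", 0L, 9L, "x"),
                        new_entity("S2", "AGE", 8L, 11L, "x"))
  m2 <- match_entities(gold, sys2, level = 1)
  expect_equal(sum(m2$counts$tp), 1L)
  expect_equal(sum(m2$counts$fp), 1L)
})

test_that("iaa_report nests and hits 1.0 for a perfect annotator", {
  ref <- generate_corpus(generator_config(n_documents = 4, seed = 13))
  ann_b <- new_corpus(lapply(ref$documents, function(d) {
    e <- d$entities
    if (nrow(e) > 0) {
      a <- e$attrs[[1]]
      if (length(a) > 0) {
        nm <- names(a)[1]
        vocab <- setdiff(attribute_schema()[[e$class[1]]][[nm]],
                         a[[nm]])
        a[[nm]] <- vocab[1]
        e$attrs[[1]] <- a
      }
    }
    new_document(d$doc_id, d$text, creation_date = d$creation_date,
                 entities = e, relationships = d$relationships)
  }))
  rep <- iaa_report(list(a = ref, b = ann_b), ref)
  a_rows <- rep[rep$annotator == "a", ]
  expect_true(all(a_rows$f1 == 1))
  b1 <- rep[rep$annotator == "b" & rep$level == 1 &
              rep$class == "overall", "f1"]
  b2 <- rep[rep$annotator == "b" & rep$level == 2 &
              rep$class == "overall", "f1"]
  expect_equal(b1, 1)  # span+class agreement unaffected by the flip
  expect_lt(b2, 1)     # attribute level strictly lower
})
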