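test_that("class distribution reproduces the corpus-marginal arithmetic", {
  corpus <- table2_corpus()
  dist <- class_distribution(corpus)
  expect_equal(attr(dist, "total"), 1540L)
  expect_equal(attr(dist, "n_documents"), 110L)
  get <- function(cl, col) dist[dist$label == cl, col]
  expect_equal(get("DISEASE_DISORDER", "count"), 688L)
  expect_equal(get("DISEASE_DISORDER", "percent"), 45)
  expect_equal(get("OTHER_EVENTS", "percent"), 23)
  expect_equal(get("TIMEX3", "percent"), 9)
  expect_equal(get("AGE", "percent"), 8)
  expect_equal(get("SUBJECT_CLASS", "percent"), 5)
  expect_equal(get("PROCEDURE", "percent"), 10)
  expect_equal(get("TIMEX3", "per_document"), 1.27)
  expect_equal(get("AGE", "per_document"), 1.08)
  # percent column sums to 100 within rounding slack
  expect_lte(abs(sum(dist$percent) - 100), nrow(dist))
})

test_that("split filtering is additive across splits", {
  corpus <- table2_corpus()
  dev <- class_distribution(corpus, splits = "development")
  tr <- class_distribution(corpus, splits = "train")
  te <- class_distribution(corpus, splits = "test")
  all <- class_distribution(corpus)
  expect_equal(dev$count + tr$count + te$count, all$count)
  expect_equal(attr(dev, "total"), 306L)
  expect_equal(attr(tr, "total"), 786L)
  expect_equal(attr(te, "total"), 448L)
  # exclude= complements splits=
  not_dev <- class_distribution(corpus, exclude = "development")
  expect_equal(not_dev$count + dev$count, all$count)
  expect_error(class_distribution(new_corpus(list())), "no documents")
})

test_that("degenerate class distributions behave", {
  one <- new_corpus(list(new_document("d", "x", entities =
    new_entity("E1", "AGE", 0L, 1L, "x"))))
  dist <- class_distribution(one)
  expect_equal(dist$percent[dist$label == "AGE"], 100)
  expect_equal(sum(dist$count), 1L)
})

test_that("SDOH distribution reproduces the training-set arithmetic", {
  dist <- sdoh_distribution(table3_corpus())
  expect_equal(attr(dist, "total"), 155L)
  get <- function(l, col) dist[dist$label == l, col]
  expect_equal(get("substance use", "count"), 87L)
  expect_equal(get("substance use", "percent"), 56)
  expect_equal(get("living situation", "percent"), 17)
  expect_equal(get("occupation", "percent"), 13)
  expect_equal(get("martial status", "percent"), 5)
  expect_equal(get("death", "percent"), 4)
  # no OTHER_EVENTS -> empty table; single type -> 100%
  empty <- sdoh_distribution(new_corpus(list(new_document("d", "x"))))
  expect_equal(nrow(empty), 0L)
  one <- new_corpus(list(new_document("d", "x", entities =
    new_entity("E1", "OTHER_EVENTS", 0L, 1L, "x",
               attrs = list(type = "death")))))
  expect_equal(sdoh_distribution(one)$percent, 100)
})

test_that("history summary reproduces the chart-review arithmetic", {
  hs <- history_summary(table4_corpus())
  sec <- hs$sections
  get <- function(s, col) sec[sec$section == s, col]
  expect_equal(get("past_medical_history", "total"), 73L)
  expect_equal(get("past_medical_history", "specified"), 34L)
  expect_equal(get("past_medical_history", "pct_specified"), 47)
  expect_equal(get("past_surgical_history", "total"), 52L)
  expect_equal(get("past_surgical_history", "pct_specified"), 65)
  expect_equal(get("family_history", "total"), 55L)
  expect_equal(get("social_history", "total"), 66L)

  fam <- hs$family
  other <- sum(fam$count[grepl("^other_", fam$label)])
  lung <- sum(fam$count[grepl("^lung_", fam$label)])
  expect_equal(other, 49L)
  expect_equal(lung, 6L)
  expect_equal(round_half_up(100 * other / (other + lung)), 89)
  expect_equal(round_half_up(100 * lung / (other + lung)), 11)
  expect_equal(fam$count[fam$label == "other_first_degree"], 31L)
  expect_equal(fam$count[fam$label == "lung_second_or_higher_degree"], 2L)

  smoke <- hs$smoking
  expect_equal(smoke$count[smoke$label == "never"], 5L)
  expect_equal(smoke$count[smoke$label == "before"], 48L)
  expect_equal(smoke$count[smoke$label == "before_overlap"], 13L)
  former_current <- sum(smoke$count[smoke$label %in%
                                      c("before", "before_overlap")])
  expect_equal(round_half_up(100 * former_current / sum(smoke$count)), 92)
})

test_that("relationship links and same-line co-occurrence both qualify as
          age/date specification", {
  # with relationships: only linked entities count
  b <- new_builder()
  emit(b, "Past Medical History:\n")
  dd1 <- emit_ent(b, "colon cancer", "DISEASE_DISORDER",
                  code = "C0007102")
  emit(b, " ")
  t1 <- emit_ent(b, "03/04/2001", "TIMEX3", attrs = list(type = "date"))
  emit(b, "\n")
  dd2 <- emit_ent(b, "asthma", "DISEASE_DISORDER", code = "C0004096")
  emit(b, " noted ")
  emit_ent(b, "05/05/2005", "TIMEX3", attrs = list(type = "date"))
  emit(b, "\n")
  emit_rel(b, dd1, t1, "DD-to-T")
  with_rels <- new_corpus(list(finish_doc(b, "rels")))
  hs <- history_summary(with_rels)
  pmh <- hs$sections[hs$sections$section == "past_medical_history", ]
  expect_equal(pmh$total, 2L)
  expect_equal(pmh$specified, 1L)  # dd2's same-line date is not linked

  # duration TIMEX3 does not qualify; date TIMEX3 on the same line does
  b2 <- new_builder()
  emit(b2, "Past Medical History:\n")
  emit_ent(b2, "asthma", "DISEASE_DISORDER", code = "C0004096")
  emit(b2, " ")
  emit_ent(b2, "for 10 years", "TIMEX3", attrs = list(type = "duration"))
  emit(b2, "\n")
  hs2 <- history_summary(new_corpus(list(finish_doc(b2, "dur"))))
  expect_equal(hs2$sections$specified[
    hs2$sections$section == "past_medical_history"], 0L)
})

test_that("half-up rounding reproduces printed table arithmetic", {
  expect_equal(round_half_up(100 * 688 / 1540), 45)
  expect_equal(round_half_up(140 / 110, 2), 1.27)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)   # base round() would give 2
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(1.005, 2), 1.01)
})
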