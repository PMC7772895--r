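test_that("numeric age expressions are detected with their type", {
  a <- detect_age("Father died of MI at age 69.")
  expect_equal(nrow(a), 1L)
  expect_identical(a$text, "age 69")  # the preposition stays outside
  expect_identical(a$attrs[[1]]$type, "fully-specified")

  cases <- list(
    c("a 61-year-old man", "61-year-old"),
    c("this 61 yo patient", "61 yo"),
    c("61yo mother has HTN", "61yo"),
    c("he is 54 y/o today", "54 y/o"),
    c("aged 54 at diagnosis", "aged 54")
  )
  for (cs in cases) {
    hit <- detect_age(cs[1])
    expect_identical(hit$text, cs[2])
    expect_identical(hit$attrs[[1]]$type, "fully-specified")
  }
})

test_that("decade and life-stage ages carry their specificity type", {
  dec <- detect_age("He is in his 70s")
  expect_identical(dec$text, "70s")
  expect_identical(dec$attrs[[1]]$type, "less-specified")
  kin <- detect_age("lung cancer in maternal uncle 70s")
  expect_identical(kin$text, "70s")
  # "70s" inside a plural year ("the 1970s") or free-floating never fires
  expect_equal(nrow(detect_age("popular in the 70s bands")), 0L)

  ev <- detect_age("Patient had childhood diabetes")
  expect_identical(ev$text, "childhood")
  expect_identical(ev$attrs[[1]]$type, "event-specified")
})

test_that("every fully-specified AGE detection contains a digit", {
  texts <- c("a 61-year-old with age 40 onset", "aged 54, 12 yo sibling",
             "childhood asthma in a 70-year-old")
  for (tx in texts) {
    hits <- detect_age(tx)
    full <- hits[vapply(hits$attrs, function(a)
      identical(a$type, "fully-specified"), logical(1)), ]
    expect_true(all(grepl("[0-9]", full$text)))
  }
})

test_that("temporal expressions are detected and typed by family", {
  t1 <- detect_timex("Arthroscopy in 1997")
  expect_identical(t1$text, "1997")
  expect_identical(t1$attrs[[1]]$type, "date")

  t2 <- detect_timex("appendectomy scheduled for next week")
  expect_identical(t2$text, "next week")
  expect_identical(t2$attrs[[1]]$type, "date")

  expect_equal(nrow(detect_timex("no temporal words here")), 0L)

  expect_identical(detect_timex("seen 2014-01-03")$attrs[[1]]$type, "date")
  expect_identical(detect_timex("on 05/13/2003")$text, "05/13/2003")
  expect_identical(detect_timex("March 2004 admission")$text, "March 2004")
  expect_identical(detect_timex("quit 10 years ago")$attrs[[1]]$type,
                   "date")
  expect_identical(detect_timex("smoked for 30 years")$attrs[[1]]$type,
                   "duration")
  expect_identical(detect_timex("1 ppd x 30 years")$attrs[[1]]$type,
                   "duration")
  expect_identical(detect_timex("checked at 3:00 pm")$attrs[[1]]$type,
                   "time")
})

test_that("numeric lookalikes are excluded from temporal matching", {
  expect_equal(nrow(detect_timex("45 pack-year smoking history")), 0L)
  expect_equal(nrow(detect_timex("Lisinopril 10 mg daily")), 0L)
  expect_equal(nrow(detect_timex("room 412, bed 2")), 0L)
  # years outside 1900-2099 are not dates
  expect_equal(nrow(detect_timex("serial number 3121")), 0L)
  # a full calendar date wins over its embedded bare year
  full <- detect_timex("admitted 2005-03-12")
  expect_identical(full$text, "2005-03-12")
})

test_that("subjects are detected with normalization and degree", {
  s <- detect_subject("father had CAD")
  expect_identical(s$text, "father")
  expect_identical(s$attrs[[1]]$implicit, "false")
  expect_identical(s$attrs[[1]]$normalization, "family_member")
  expect_identical(s$attrs[[1]]$degree_relation, "1")

  fam <- detect_subject("family history: notable for CAD")
  expect_identical(fam$text[1], "family")
  expect_identical(fam$attrs[[1]]$implicit, "true")

  wife <- detect_subject("lives with wife")
  expect_identical(wife$attrs[[1]]$normalization, "other")
  expect_identical(wife$attrs[[1]]$degree_relation,
                   "not_biologically_related")

  mu <- detect_subject("lung cancer in maternal uncle")
  expect_identical(mu$text, "maternal uncle")
  expect_identical(mu$attrs[[1]]$degree_relation, "2")
})

test_that("run_rule_ner scans history sections only and is deterministic", {
  txt <- paste0("Seen by a 45-year-old resident in 2013.\n",
                "Family History:\n61yo mother has HTN.\n")
  doc <- run_rule_ner(new_document("d", txt))
  # nothing from the leading other section
  secs <- tag_sections(txt)
  fh_start <- secs$header_start[secs$label == "family_history"]
  expect_true(all(doc$entities$start >= fh_start))
  expect_setequal(doc$entities$text[doc$entities$class == "AGE"], "61yo")
  expect_true("mother" %in%
                doc$entities$text[doc$entities$class == "SUBJECT_CLASS"])
  # spans never cross the section boundary and rerunning is identical
  doc2 <- run_rule_ner(new_document("d", txt))
  expect_identical(doc$entities, doc2$entities)
  expect_identical(validate_document(doc), character(0))
})

test_that("documents without history sections pass through unchanged", {
  doc <- new_document("d", "A note with age 40 but no headers.")
  out <- run_rule_ner(doc)
  expect_equal(nrow(out$entities), 0L)
})

test_that("same-class overlaps resolve longest-first then leftmost", {
  # "age 69" (capture rule) vs "69" alternatives: single maximal span
  hits <- detect_age("at age 69")
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$text, "age 69")
  # two disjoint matches are both kept, in offset order
  two <- detect_timex("CABG 1994 and appendectomy 2001")
  expect_identical(two$text, c("1994", "2001"))
})
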