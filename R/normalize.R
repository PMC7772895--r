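# Attribute normalizers: age ranges and birth-time ranges, degree of
# biological relation, TIMEX3 type classification, and DocTimeRel defaults.
# All default tables live here, in one place, so changing a default changes
# every downstream entity uniformly.

#' Life-stage age table
#'
#' Numeric bounds (in years) for event-specified age terms. The schema
#' defines the event-specified category but no numeric map, so these bounds
#' are package conventions: childhood 0-12, infancy 0-1, adolescence /
#' teenage years 13-19. Pass a modified table to [normalize_age()] to
#' override.
#'
#' @return Data frame with columns `term`, `start_age`, `end_age`.
#' @export
life_stage_table <- function() {
  data.frame(
    term = c("childhood", "infancy", "infant", "adolescence", "teenager",
             "teens"),
    start_age = c(0L, 0L, 0L, 13L, 13L, 13L),
    end_age = c(12L, 1L, 1L, 19L, 19L, 19L),
    stringsAsFactors = FALSE
  )
}

#' Kinship degree table
#'
#' Degree of biological relation by kin term, based on genetic similarity to
#' the patient: degree 0 identical twin (relatedness 1), degree 1 parent /
#' sibling / offspring (1/2), degree 2 grandparent / aunt / uncle / niece /
#' nephew / half-sibling / grandchild (1/4), degree 3 first cousin /
#' great-grandparent (1/8). Spouses, in-laws, adoptive relations, and donors
#' map to `not_biologically_related` or `unknown`; the unspecific terms
#' "family" and "relative" map to `unknown`.
#'
#' @return Named character vector: kin term -> degree value.
#' @export
kinship_table <- function() {
  deg <- function(terms, value) stats::setNames(rep(value, length(terms)),
                                                terms)
  c(
    deg("identical twin", "0"),
    deg(c("mother", "father", "mom", "dad", "parent", "parents",
          "brother", "sister", "sibling", "siblings", "twin",
          "son", "daughter", "offspring"), "1"),
    deg(c("grandmother", "grandfather", "grandparent", "grandparents",
          "grandson", "granddaughter", "grandchild",
          "aunt", "uncle", "niece", "nephew",
          "half-brother", "half-sister", "half-sibling"), "2"),
    deg(c("cousin", "first cousin", "great-grandmother",
          "great-grandfather", "great-grandparent"), "3"),
    deg(c("wife", "husband", "spouse", "in-law", "mother-in-law",
          "father-in-law", "stepmother", "stepfather", "adoptive mother",
          "adoptive father"), "not_biologically_related"),
    deg(c("family", "relative", "relatives", "donor"), "unknown")
  )
}

#' Degree of biological relation for a subject term
#'
#' Case-insensitive lookup in [kinship_table()]; the side-of-family
#' modifiers `maternal`/`paternal` are stripped without changing the degree
#' (a maternal uncle is as related as a paternal one). Unknown terms map to
#' `"unknown"`.
#'
#' @param term Subject surface term, e.g. `"Sister"`, `"maternal uncle"`.
#' @param table Kinship table override.
#' @return Degree value as a string: `"0"`..`"3"`,
#'   `"not_biologically_related"`, or `"unknown"`.
#' @export
#' @examples
#' degree_relation("Sister")          # "1"
#' degree_relation("maternal uncle")  # "2"
degree_relation <- function(term, table = kinship_table()) {
  key <- trimws(tolower(term))
  key <- sub("^(maternal|paternal)\\s+", "", key)
  val <- unname(table[key])
  val[is.na(val)] <- "unknown"
  val
}

#' Normalize an AGE entity to an age range
#'
#' Fully-specified ages normalize to a degenerate range (`"age 69"` ->
#' `[69, 69]`), less-specified decades to a 10-year range (`"70s"` ->
#' `[70, 79]`), and event-specified life stages via [life_stage_table()]
#' (`"childhood"` -> `[0, 12]`).
#'
#' @param age_entity One-row AGE entity frame (with its `type` attribute
#'   set), or a character surface form together with `type`.
#' @param type Age type when `age_entity` is a plain string.
#' @param stages Life-stage table override.
#' @return List with integer `start_age`, `end_age`, or `NULL` when the
#'   surface form cannot be resolved (e.g. a life stage missing from the
#'   table).
#' @export
#' @examples
#' normalize_age("70s", type = "less-specified")
normalize_age <- function(age_entity, type = NULL,
                          stages = life_stage_table()) {
  if (is.data.frame(age_entity)) {
    stopifnot(nrow(age_entity) == 1L, age_entity$class == "AGE")
    text <- age_entity$text
    type <- age_entity$attrs[[1L]]$type
  } else {
    text <- age_entity
  }
  stopifnot(!is.null(type))
  if (type == "fully-specified") {
    n <- regmatches(text, regexpr("\\d{1,3}", text))
    if (length(n) == 0L) return(NULL)
    a <- as.integer(n)
    return(list(start_age = a, end_age = a))
  }
  if (type == "less-specified") {
    n <- regmatches(text, regexpr("\\d{1,3}(?=s\\b)", text, perl = TRUE))
    if (length(n) == 0L) return(NULL)
    a <- as.integer(n)
    return(list(start_age = a, end_age = a + 9L))
  }
  key <- trimws(tolower(text))
  i <- match(key, stages$term)
  if (is.na(i)) return(NULL)
  list(start_age = stages$start_age[i], end_age = stages$end_age[i])
}

# Calendar-aware year subtraction; Feb 29 minus N years lands on Feb 28
# when the target year is not a leap year.
subtract_years <- function(date, n) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year - n
  out <- suppressWarnings(as.Date(lt))
  feb29 <- format(date, "%m-%d") == "02-29"
  fix <- feb29 & (is.na(out) | format(out, "%m-%d") != "02-29")
  if (any(fix)) {
    out[fix] <- as.Date(sprintf("%04d-02-28",
                                as.POSIXlt(date[fix])$year + 1900L - n))
  }
  out
}

#' Convert an age range to a birth-era time range
#'
#' Anchored at a reference date (the document creation date), an age range
#' `[a, b]` maps to the calendar range in which the subject of that age was
#' born or the event occurred: `start_date = reference - b years`,
#' `end_date = reference - a years`. A `[70, 79]` range referenced at
#' 2029-10-10 yields `[1950-10-10, 1959-10-10]`.
#'
#' @param age_range List with `start_age`, `end_age` (see
#'   [normalize_age()]).
#' @param reference_date Reference [Date]; an error is raised when missing,
#'   signalling that time normalization is unavailable for the document.
#' @return List with `start_date`, `end_date` ([Date]s,
#'   `start_date <= end_date`).
#' @export
#' @examples
#' age_to_time_range(list(start_age = 70, end_age = 79),
#'                   as.Date("2029-10-10"))
age_to_time_range <- function(age_range, reference_date) {
  if (is.null(reference_date) || length(reference_date) == 0L ||
      is.na(reference_date)) {
    stop("reference date unavailable: cannot normalize age to a time range")
  }
  reference_date <- as.Date(reference_date)
  list(start_date = subtract_years(reference_date, age_range$end_age),
       end_date = subtract_years(reference_date, age_range$start_age))
}

#' DocTimeRel default table
#'
#' Majority DocTimeRel values assigned by default so annotators (and the
#' automated pipeline) only override the exceptions: disorders default to
#' `before_overlap` (chronic conditions dominate past medical histories),
#' procedures to `before` (histories record completed interventions), other
#' events to `before_overlap`.
#'
#' @return Data frame with columns `class`, `value`.
#' @export
doctimerel_defaults <- function() {
  data.frame(
    class = c("DISEASE_DISORDER", "PROCEDURE", "OTHER_EVENTS"),
    value = c("before_overlap", "before", "before_overlap"),
    stringsAsFactors = FALSE
  )
}

#' Default DocTimeRel value for an entity
#'
#' @param entity_class `DISEASE_DISORDER`, `PROCEDURE`, or `OTHER_EVENTS`.
#' @param section_label Section label of the mention (available for
#'   section-specific overrides in custom tables; the shipped defaults are
#'   uniform per class).
#' @param defaults Default table, see [doctimerel_defaults()]. A `section`
#'   column, when present, takes precedence over class-wide rows.
#' @return A DocTimeRel value string.
#' @export
#' @examples
#' default_doctimerel("DISEASE_DISORDER", "past_medical_history")
#' default_doctimerel("PROCEDURE", "past_surgical_history")
default_doctimerel <- function(entity_class, section_label = NA_character_,
                               defaults = doctimerel_defaults()) {
  stopifnot(entity_class %in% c("DISEASE_DISORDER", "PROCEDURE",
                                "OTHER_EVENTS"))
  if ("section" %in% names(defaults)) {
    hit <- which(defaults$class == entity_class &
                   !is.na(defaults$section) &
                   defaults$section == section_label)
    if (length(hit) > 0L) return(defaults$value[hit[1L]])
    hit <- which(defaults$class == entity_class & is.na(defaults$section))
    return(defaults$value[hit[1L]])
  }
  defaults$value[match(entity_class, defaults$class)]
}

#' Classify a TIMEX3 surface form
#'
#' Assigns the TIMEX3 `type` attribute from the surface string: clock forms
#' are `time`, duration forms ("for 10 years", "x 30 years", "10-year")
#' are `duration`, calendar and relative forms are `date`. Unmatched strings
#' fall back to `date`, the majority type.
#'
#' @param timex_text TIMEX3 surface string.
#' @return One of `"date"`, `"time"`, `"duration"`.
#' @export
#' @examples
#' classify_timex_type("1997")
#' classify_timex_type("for 10 years")
classify_timex_type <- function(timex_text) {
  vapply(timex_text, function(x) {
    if (grepl("\\b\\d{1,2}:\\d{2}\\b", x)) return("time")
    if (grepl("^\\s*(for|x)\\b", x, ignore.case = TRUE) ||
        grepl("\\d[- ]year\\b(?!-old)", x, perl = TRUE,
              ignore.case = TRUE)) {
      return("duration")
    }
    "date"
  }, character(1), USE.NAMES = FALSE)
}
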