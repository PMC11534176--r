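note_label <- function(text) categorize_note(text)

test_that("review example phrases receive their documented categories", {
  cases <- c(
    "Gunshot wound of the right lower leg."                  = "exposure",
    "She hears gunshots at night."                           = "exposure",
    "Pt. suffered a GSW."                                    = "exposure",
    "Pt. was robbed at gunpoint."                            = "exposure",
    "History of gunshot injury."                             = "exposure",
    "No access to firearms."                                 = "assessment",
    "Do you have any guns in the home? No"                   = "assessment",
    "Denies SI; no guns."                                    = "assessment",
    "Remove guns from the home."                             = "guidance_education",
    "Make sure any guns in the home are locked up."          = "guidance_education",
    "Gun safety: education done."                            = "guidance_education",
    "...shooting pain all the way down."                     = "treatment_care",
    "Shot of Hepatitis A."                                   = "treatment_care",
    "Here for dmpa shot only."                               = "treatment_care",
    "...cortisone shot in left knee"                         = "treatment_care",
    "[Shot for Birth Control: Care Instructions.]"           = "template_shot",
    "Seen by Dr. Gunther for follow-up."                     = "name_contains_term",
    "Shot a nailgun"                                         = "other",
    "Snap shot includes current meds/allergies/problem list" = "other")
  got <- vapply(names(cases), note_label, character(1))
  expect_equal(unname(got), unname(cases))
})

test_that("match-level labels feed note-level precedence (exposure first)", {
  m <- find_matches("Provider name includes Gunther", default_lexicon())
  mm <- categorize_matches(m)
  expect_equal(mm$match_category, "name_contains_term")

  # two matches with different labels resolve by precedence
  txt <- "She hears gunshots at night. No guns in the home."
  mm2 <- categorize_matches(find_matches(txt, default_lexicon()))
  expect_true("exposure" %in% mm2$match_category)
  expect_true("assessment" %in% mm2$match_category)
  expect_equal(categorize_notes(mm2)$category, "exposure")

  # exactly one label per note, always a known category
  expect_length(categorize_notes(mm2)$category, 1)
  expect_error(categorize_note("BP stable."), "no lexicon matches")
})

test_that("categorization is deterministic and total on generated corpora", {
  pop <- generate_population(generator_config(n_patients = 120, seed = 21))
  s <- search_corpus(pop$notes, default_lexicon())
  l1 <- categorize_notes(s)
  l2 <- categorize_notes(s)
  expect_identical(l1, l2)
  expect_true(all(l1$category %in% note_categories()))
  expect_equal(nrow(l1), nrow(s$note_hits))
})

test_that("refinement filters remove confounders with the documented reasons", {
  texts <- c(T1 = "[Shot for Birth Control: Care Instructions.]",
             T2 = "Shot of Hepatitis A.",
             T3 = "...shooting pain all the way down",
             T4 = "Seen by Dr. Gunther",
             K1 = "...suffered a GSW.",
             K2 = "Pt. was robbed at gunpoint.",
             K3 = "Gunshot wound of the right lower leg.")
  notes <- data.frame(note_id = names(texts), patient_id = names(texts),
                      date = "2020-01-01", note_type = "pc", text = unname(texts))
  s <- search_corpus(notes, default_lexicon())
  r <- apply_refinement_filters(s)
  expect_equal(nrow(r$kept) + nrow(r$removed), nrow(s$matches))
  expect_equal(nrow(merge(as.data.frame(r$kept), as.data.frame(r$removed),
                          by = c("note_id", "start", "end", "surface"))), 0)

  reason_of <- function(id, surf) {
    r$removed$reason[r$removed$note_id == id & r$removed$surface == surf]
  }
  expect_equal(reason_of("T1", "shot"), "template_phrase")
  expect_equal(reason_of("T2", "shot"), "injection_shot")
  expect_equal(reason_of("T3", "shooting"), "pain_shooting")
  expect_equal(reason_of("T4", "gun"), "proper_name")

  # true exposure notes keep at least one match each
  for (id in c("K1", "K2", "K3")) {
    expect_gte(sum(r$kept$note_id == id), 1)
  }
})

test_that("a note whose matches are all removed is never labeled exposure", {
  pop <- generate_population(generator_config(n_patients = 250, seed = 31))
  s <- search_corpus(pop$notes, default_lexicon())
  r <- apply_refinement_filters(s)
  gone <- setdiff(unique(s$matches$note_id), unique(r$kept$note_id))
  if (length(gone) > 0) {
    labels <- categorize_notes(s)
    expect_false(any(labels$category[labels$note_id %in% gone] == "exposure"))
  }
  expect_gt(length(gone), 0)  # generated corpora do contain pure confounders
})

test_that("rule sets round-trip through YAML and validate their precedence", {
  rules <- default_rules()
  path <- withr::local_tempfile(fileext = ".yml")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(back$cues, rules$cues)
  expect_equal(back$note_precedence, rules$note_precedence)
  expect_equal(back$template_phrases, rules$template_phrases)

  expect_error(rule_set(cues = list(), match_order = c("exposure", "other"),
                        note_precedence = note_categories()),
               "permutation")
})
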