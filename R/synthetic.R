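# --- note templates ----------------------------------------------------------

# Phrase templates per context category, patterned on how firearm terms
# actually appear in ambulatory notes: exposure narratives, risk
# assessments, anticipatory guidance, injection/pain care, EHR template
# phrases, provider surnames containing "gun", and miscellaneous
# confounders. {slot} placeholders are filled at generation time. The
# shipped rule set recovers each template's category exactly, which is
# what makes generated corpora usable as labeled ground truth.
note_templates <- function() {
  list(
    exposure = c(
      "She hears gunshots at night near {place}.",
      "Gunshot wound of the {side} {site}.",
      "Pt. suffered a GSW to the {side} {site}.",
      "Pt. was robbed at gunpoint last {time}.",
      "History of gunshot injury, {year}.",
      "He recalls a stranger sticking a gun in his mouth."
    ),
    assessment = c(
      "No access to firearms at this time.",
      "Do you have any guns in the home? No.",
      "Denies SI and HI; no guns in the house.",
      "Talks or writes about death, including talking about guns, knives or pills? No.",
      "Pt reports guns in the home. Locked up."
    ),
    guidance_education = c(
      "Remove guns from the home.",
      "Make sure any guns in the home are locked up.",
      "Gun safety: education done with {relative}.",
      "Keep opioids under lock and key; they are more dangerous than blasting caps, and guns."
    ),
    treatment_care = c(
      "Shooting pain all the way down the {side} leg.",
      "Shot of Hepatitis A administered today.",
      "Here for dmpa shot only.",
      "Cortisone shot in {side} {site}.",
      "Flu shot given; no adverse reaction."
    ),
    template_shot = c(
      "[Shot for Birth Control: Care Instructions.] {extra}",
      "[Flu Shot: Care Instructions.] {extra}"
    ),
    name_contains_term = c(
      "Seen by Dr. {provider} for follow-up.",
      "Appointment scheduled with Dr. {provider}."
    ),
    other = c(
      "Shot a nailgun at work; no injury reported.",
      "Snap shot includes current meds, allergies, and problem list."
    )
  )
}

# Decoy texts contain no lexicon term at all (including as a substring).
decoy_templates <- function() {
  c("Follow up for hypertension; medications refilled.",
    "Annual wellness visit completed. No acute concerns.",
    "Discussed diet and exercise goals with patient.",
    "Patient called to reschedule appointment.",
    "Labs reviewed; all within normal limits.")
}

template_fillers <- function() {
  list(site = c("knee", "shoulder", "forearm", "lower leg", "hip", "ankle"),
       side = c("left", "right"),
       relative = c("her mother", "his father", "their cousin", "her brother"),
       provider = c("Gunther", "Gunnarson", "Gundersen", "Gunderman"),
       place = c("her apartment", "the bus stop", "his neighborhood",
                 "the parking lot"),
       year = as.character(2012:2021),
       time = c("week", "month", "night", "year"),
       extra = c("Reviewed with patient.", "Documented in chart.",
                 "Patient verbalized understanding."))
}

# Fill {slot} placeholders with uniformly drawn fillers (consumes RNG).
fill_template <- function(template, fillers = template_fillers()) {
  slots <- stringi::stri_extract_all_regex(template, "\\{[a-z]+\\}")[[1]]
  if (length(slots) == 1 && is.na(slots)) return(template)
  for (slot in slots) {
    key <- gsub("[{}]", "", slot)
    pool <- fillers[[key]]
    if (is.null(pool)) abort(sprintf("unknown template slot: %s", slot))
    template <- stringi::stri_replace_first_fixed(
      template, slot, pool[sample.int(length(pool), 1L)])
  }
  template
}

# --- configuration -----------------------------------------------------------

#' Synthetic EHR generator configuration
#'
#' Defaults reproduce the documented study conditions: indication sources
#' mixing 66.4% ICD-only, 33.3% SmartForm-only and 0.3% both; structured
#' event dates inside the 2012-2022 ICD window and the Feb-Dec 2022
#' SmartForm window; note context categories mixed in the proportions of
#' the 90-note chart review (13/36/20/16/2/2/1 over 90); 1-5 notes per
#' patient; and 30% decoy notes containing no firearm term so that search
#' filtering is exercised.
#'
#' @param n_patients Number of patients (>= 1).
#' @param indication_mixture Named proportions over `icd`, `smartform`,
#'   `both`; must be non-negative and sum to 1.
#' @param notes_per_patient Length-2 integer vector (min, max); notes per
#'   patient are uniform on that range.
#' @param category_mixture Named proportions over [note_categories()] for
#'   non-decoy notes; non-negative, sum to 1.
#' @param decoy_fraction Proportion of notes with no firearm term.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1000,
                             indication_mixture = c(icd = 0.664,
                                                    smartform = 0.333,
                                                    both = 0.003),
                             notes_per_patient = c(1L, 5L),
                             category_mixture = c(exposure = 13, assessment = 36,
                                                  guidance_education = 20,
                                                  treatment_care = 16,
                                                  template_shot = 2,
                                                  name_contains_term = 2,
                                                  other = 1) / 90,
                             decoy_fraction = 0.3,
                             seed = 1L) {
  if (n_patients < 1) abort("`n_patients` must be >= 1.")
  check_mixture <- function(m, names_expected, what) {
    if (!setequal(names(m), names_expected)) {
      abort(sprintf("`%s` must be named over: %s", what,
                    paste(names_expected, collapse = ", ")))
    }
    m <- m[names_expected]
    if (any(m < 0)) abort(sprintf("degenerate mixture: `%s` has a negative proportion.", what))
    if (abs(sum(m) - 1) > 1e-9) abort(sprintf("`%s` must sum to 1.", what))
    m
  }
  indication_mixture <- check_mixture(indication_mixture,
                                      c("icd", "smartform", "both"),
                                      "indication_mixture")
  category_mixture <- check_mixture(category_mixture, note_categories(),
                                    "category_mixture")
  if (length(notes_per_patient) != 2L || notes_per_patient[1] < 1 ||
      notes_per_patient[1] > notes_per_patient[2]) {
    abort("`notes_per_patient` must be c(min, max) with 1 <= min <= max.")
  }
  if (decoy_fraction < 0 || decoy_fraction >= 1) {
    abort("`decoy_fraction` must be in [0, 1).")
  }
  structure(list(n_patients = as.integer(n_patients),
                 indication_mixture = indication_mixture,
                 notes_per_patient = as.integer(notes_per_patient),
                 category_mixture = category_mixture,
                 decoy_fraction = decoy_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# --- population generator ----------------------------------------------------

rand_date <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

qualifying_icd_codes <- function() {
  c("W34.00XA", "W32.0XXA", "X72.XXXA", "X93.XXXA", "X94.8XXA",
    "X95.09XA", "Y22.XXXA", "W33.00XA")
}

filler_icd_codes <- function() c("F43.10", "I10", "Z00.00", "E11.9", "J45.909")

#' Generate a synthetic EHR population
#'
#' Produces structured records (ICD and SmartForm event tables) and
#' free-text clinical notes with known ground truth, so the whole pipeline
#' — cohort, search, sampling, categorization, reporting — can run and be
#' verified without patient data. Every patient receives an indication
#' source drawn from the configured mixture, qualifying events dated
#' inside the study windows, and non-qualifying filler events; notes are
#' either decoys (no firearm term; a few empty, as refill requests are)
#' or instantiated from a category template, with ground-truth spans
#' recorded as found by [find_matches()] under the default lexicon.
#' Output is byte-identical for identical configs (seed included).
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_population`: `patients` (patient_id,
#'   indication_source), `icd_events`, `smartform_events`, `notes`
#'   (note_id, patient_id, date, note_type, text), `truth` (note_id,
#'   truth_category; `"none"` for decoys), `spans` (note_id, start, end,
#'   surface), and the `config`.
#' @export
generate_population <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  templates <- note_templates()
  fillers <- template_fillers()

  with_seed(config$seed, {
    n <- config$n_patients
    patient_id <- sprintf("P%05d", seq_len(n))
    src <- sample(names(config$indication_mixture), n, replace = TRUE,
                  prob = config$indication_mixture)

    # structured events: qualifying per source, plus benign filler diagnoses
    icd_pat <- patient_id[src %in% c("icd", "both")]
    icd_events <- tibble(
      patient_id = icd_pat,
      code = sample(qualifying_icd_codes(), length(icd_pat), replace = TRUE),
      date = rand_date(length(icd_pat), "2012-01-01", "2022-12-31"))
    filler_pat <- patient_id[runif(n) < 0.5]
    icd_events <- bind_rows(icd_events, tibble(
      patient_id = filler_pat,
      code = sample(filler_icd_codes(), length(filler_pat), replace = TRUE),
      date = rand_date(length(filler_pat), "2012-01-01", "2022-12-31")))

    sf_pat <- patient_id[src %in% c("smartform", "both")]
    smartform_events <- tibble(
      patient_id = sf_pat,
      value = sample(c("recent", "historical"), length(sf_pat), replace = TRUE),
      date = rand_date(length(sf_pat), "2022-02-01", "2022-12-31"))
    # non-qualifying SmartForm answers for a slice of the ICD-only patients
    none_pat <- patient_id[src == "icd" & runif(n) < 0.2]
    smartform_events <- bind_rows(smartform_events, tibble(
      patient_id = none_pat,
      value = sample(c("none", "unknown"), length(none_pat), replace = TRUE),
      date = rand_date(length(none_pat), "2022-02-01", "2022-12-31")))

    # notes
    k <- sample(seq(config$notes_per_patient[1], config$notes_per_patient[2]),
                n, replace = TRUE)
    note_pat <- rep(patient_id, k)
    n_notes <- length(note_pat)
    note_id <- sprintf("N%06d", seq_len(n_notes))
    is_decoy <- runif(n_notes) < config$decoy_fraction
    truth_category <- ifelse(is_decoy, "none",
                             sample(names(config$category_mixture), n_notes,
                                    replace = TRUE,
                                    prob = config$category_mixture))
    text <- character(n_notes)
    for (i in seq_len(n_notes)) {
      if (is_decoy[i]) {
        # a small share of decoys are empty refill-request notes
        text[i] <- if (runif(1) < 0.05) "" else
          sample(decoy_templates(), 1L)
      } else {
        tpl <- templates[[truth_category[i]]]
        text[i] <- fill_template(tpl[sample.int(length(tpl), 1L)], fillers)
      }
    }
    note_type <- sample(c("primary care", "behavioral health", "refill request"),
                        n_notes, replace = TRUE)
    note_type[!nzchar(text)] <- "refill request"
    notes <- tibble(note_id = note_id, patient_id = note_pat,
                    date = rand_date(n_notes, "2012-01-01", "2022-12-31"),
                    note_type = note_type, text = text)
  })

  spans <- locate_matches(notes$text, notes$note_id, notes$patient_id,
                          default_lexicon(), mode = "substring", window = 60) |>
    select("note_id", "start", "end", "surface")

  structure(list(patients = tibble(patient_id = patient_id,
                                   indication_source = src),
                 icd_events = icd_events,
                 smartform_events = smartform_events,
                 notes = notes,
                 truth = tibble(note_id = note_id,
                                truth_category = truth_category),
                 spans = spans,
                 config = config),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("<synthetic EHR population: %d patients, %d notes (%d decoys), seed %d>\n",
              nrow(x$patients), nrow(x$notes),
              sum(x$truth$truth_category == "none"), x$config$seed))
  invisible(x)
}

# --- 90-note chart-review fixture -------------------------------------------

#' The 90-note chart-review fixture
#'
#' Builds the fixed-composition review set: 90 labeled notes from 90
#' distinct patients with category counts exposure 13, assessment 36,
#' guidance/education 20, treatment/care 16, and the three small cells
#' split 2 (template "shot") / 2 (name) / 1 (other) — the published
#' distribution, with the three suppressed cells (known only to be < 10
#' each and to sum to 5) fixed at 2/2/1. Texts instantiate each
#' category's phrase templates; the seed only randomizes slot fillers
#' and row order, never the category counts.
#'
#' @param seed Integer seed.
#' @return A tibble of class `labeled_notes` with note fields plus
#'   `truth_category`.
#' @export
#' @examples
#' table(make_table3_fixture(seed = 7)$truth_category)
make_table3_fixture <- function(seed = 7) {
  counts <- c(exposure = 13L, assessment = 36L, guidance_education = 20L,
              treatment_care = 16L, template_shot = 2L,
              name_contains_term = 2L, other = 1L)
  templates <- note_templates()
  fillers <- template_fillers()
  cats <- rep(names(counts), counts)

  with_seed(seed, {
    text <- character(length(cats))
    for (i in seq_along(cats)) {
      tpl <- templates[[cats[i]]]
      # cycle templates within a category so each appears; fillers random
      j <- (sum(cats[seq_len(i)] == cats[i]) - 1L) %% length(tpl) + 1L
      text[i] <- fill_template(tpl[j], fillers)
    }
    ord <- sample.int(length(cats))
    out <- tibble(
      note_id = sprintf("FN%04d", seq_along(cats)),
      patient_id = sprintf("FP%04d", seq_along(cats)),
      date = rand_date(length(cats), "2012-01-01", "2022-12-31"),
      note_type = sample(c("primary care", "behavioral health"),
                         length(cats), replace = TRUE),
      text = text[ord],
      truth_category = cats[ord])
  })
  attr(out, "seed") <- seed
  class(out) <- c("labeled_notes", class(out))
  out
}

# --- privacy guard -----------------------------------------------------------

#' Assert generated text contains no real-PHI-like strings
#'
#' Scans texts against a denylist of identifier patterns (SSNs, phone
#' numbers, MRN-style tags, email addresses by default). All names, dates
#' and identifiers in this package are synthesized, and the test suite
#' runs this guard over every generated corpus.
#'
#' @param texts Character vector.
#' @param patterns Character vector of regex patterns to forbid.
#' @return `TRUE` invisibly; errors listing offending patterns otherwise.
#' @export
assert_no_phi <- function(texts, patterns = phi_patterns()) {
  for (p in patterns) {
    hit <- stringi::stri_detect_regex(texts, p)
    if (any(hit, na.rm = TRUE)) {
      abort(sprintf("generated text matches PHI denylist pattern '%s': %s",
                    p, utils::head(texts[which(hit)], 1)))
    }
  }
  invisible(TRUE)
}

#' @rdname assert_no_phi
#' @export
phi_patterns <- function() {
  c("\\b\\d{3}-\\d{2}-\\d{4}\\b",          # SSN
    "\\(\\d{3}\\)\\s?\\d{3}-\\d{4}",        # phone
    "\\bMRN[:# ]?\\d+",                       # medical record number
    "[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}")  # email
}
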