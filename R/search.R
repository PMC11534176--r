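#' Search a note corpus for firearm terms
#'
#' Applies the lexicon to every note, returning per-match offsets, per-note
#' hit summaries, and distinct-patient counts overall and per term
#' category. A patient counts toward a category if any of their notes
#' contains a match of that category; hits are computed per note, never
#' pooled across notes. Notes with empty (or missing) text are skipped
#' silently and counted in `n_empty_skipped` — refill-request notes are
#' often empty.
#'
#' @param notes Data frame with columns `note_id`, `patient_id`, `text`
#'   (other columns such as `date`, `note_type` are carried along
#'   unchecked). `note_id` must be unique.
#' @inheritParams find_matches
#' @return An object of class `corpus_search` with elements
#'   \describe{
#'     \item{matches}{tibble of term matches (see [find_matches()]) with
#'       `note_id` and `patient_id`}
#'     \item{note_hits}{one row per note with >= 1 match: `note_id`,
#'       `patient_id`, `n_matches`, `categories_hit` (list column)}
#'     \item{patient_counts}{distinct patients per term category}
#'     \item{n_patients_hit}{distinct patients with any hit}
#'   }
#'   plus corpus bookkeeping (`n_notes`, `n_patients`, `n_notes_hit`,
#'   `n_empty_skipped`, `mode`, `window`).
#' @export
#' @examples
#' notes <- data.frame(note_id = c("N1", "N2"), patient_id = c("P1", "P2"),
#'                     text = c("Pt. was robbed at gunpoint.", "BP stable."))
#' search_corpus(notes, default_lexicon())
search_corpus <- function(notes, lexicon = default_lexicon(),
                          mode = c("substring", "word_boundary"),
                          window = 60) {
  mode <- match.arg(mode)
  assert_columns(notes, c("note_id", "patient_id", "text"), "notes")
  notes <- as_tibble(notes)
  if (anyDuplicated(notes$note_id)) {
    abort(sprintf("duplicate note_id in corpus: %s",
                  paste(unique(notes$note_id[duplicated(notes$note_id)]),
                        collapse = ", ")))
  }
  txt <- ifelse(is.na(notes$text), "", notes$text)
  nonempty <- nzchar(txt)
  matches <- locate_matches(texts = txt[nonempty],
                            note_ids = notes$note_id[nonempty],
                            patient_ids = notes$patient_id[nonempty],
                            lexicon = lexicon, mode = mode, window = window)

  note_hits <- matches |>
    group_by(.data$note_id, .data$patient_id) |>
    summarise(n_matches = n(),
              categories_hit = list(sort(unique(.data$category))),
              .groups = "drop")

  patient_counts <- matches |>
    distinct(.data$patient_id, category = factor(.data$category,
                                                 levels = term_categories())) |>
    count(.data$category, name = "n_patients") |>
    complete(category, fill = list(n_patients = 0L)) |>
    mutate(category = as.character(.data$category))

  structure(list(matches = matches,
                 note_hits = note_hits,
                 patient_counts = patient_counts,
                 n_patients_hit = n_distinct(matches$patient_id),
                 n_notes = nrow(notes),
                 n_patients = n_distinct(notes$patient_id),
                 n_notes_hit = nrow(note_hits),
                 n_empty_skipped = sum(!nonempty),
                 mode = mode, window = window,
                 lexicon_version = attr(lexicon, "version_label")),
            class = "corpus_search")
}

#' @export
print.corpus_search <- function(x, ...) {
  cat(sprintf(paste0("<corpus search (%s mode): %d/%d notes with >=1 match; ",
                     "%d/%d distinct patients; %d matches; %d empty notes skipped>\n"),
              x$mode, x$n_notes_hit, x$n_notes, x$n_patients_hit, x$n_patients,
              nrow(x$matches), x$n_empty_skipped))
  print(x$patient_counts, ...)
  invisible(x)
}
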