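#' Stratified random sample of notes by term category
#'
#' Draws `n_per_category` notes for each term category (broad, gun-only,
#' shooting) such that every sampled note contains a match of its stratum's
#' category, each patient contributes at most one note, and patients are
#' distinct across strata — the chart-review design of one note per patient
#' and 3 x n distinct patients in total.
#'
#' Strata are processed sequentially in fixed order (broad, gun_only,
#' shooting): eligible patients are those with at least one note hitting
#' the category, excluding patients already consumed by an earlier stratum;
#' patients are drawn uniformly without replacement, then one qualifying
#' note per chosen patient uniformly. Eligibility lists are sorted by
#' (patient_id, note_id) before drawing, so the plan depends only on the
#' seed and the set of hits, not on input row order. A stratum with fewer
#' eligible patients than requested raises an error naming the category and
#' the shortfall; infeasibility is never silently relaxed.
#'
#' @param hits A `corpus_search` object from [search_corpus()], or a match
#'   tibble with columns `note_id`, `patient_id`, `category`.
#' @param n_per_category Number of notes per term category (>= 1).
#' @param seed Integer seed; the same seed and hits give an identical plan.
#' @return A tibble of class `sample_plan` with columns `category`,
#'   `patient_id`, `note_id` and attribute `seed`.
#' @export
stratified_sample <- function(hits, n_per_category = 30, seed = 1) {
  if (inherits(hits, "corpus_search")) hits <- hits$matches
  assert_columns(hits, c("note_id", "patient_id", "category"), "hits")
  if (n_per_category < 1) abort("`n_per_category` must be >= 1.")
  elig <- hits |>
    distinct(.data$category, .data$patient_id, .data$note_id) |>
    arrange(.data$category, .data$patient_id, .data$note_id)

  chosen <- character(0)
  rows <- list()
  with_seed(seed, {
    for (cat in term_categories()) {
      cat_elig <- filter(elig, .data$category == cat,
                         !(.data$patient_id %in% chosen))
      patients <- sort(unique(cat_elig$patient_id))
      if (length(patients) < n_per_category) {
        abort(sprintf(paste0("insufficient eligible distinct patients for ",
                             "category '%s': need %d, have %d (shortfall %d)"),
                      cat, n_per_category, length(patients),
                      n_per_category - length(patients)),
              class = "fa_sampling_infeasible")
      }
      sel <- patients[sample.int(length(patients), n_per_category)]
      note_for <- map_chr(sel, function(p) {
        nts <- sort(cat_elig$note_id[cat_elig$patient_id == p])
        nts[sample.int(length(nts), 1L)]
      })
      chosen <- c(chosen, sel)
      rows[[cat]] <- tibble(category = cat, patient_id = sel, note_id = note_for)
    }
  })
  plan <- list_rbind(rows)
  attr(plan, "seed") <- seed
  class(plan) <- c("sample_plan", class(plan))
  plan
}

#' Write / read a sample plan
#'
#' The plan is stored as a tab-delimited table (`category`, `patient_id`,
#' `note_id`) preceded by a `# seed: <n>` comment so a review sample can be
#' reproduced exactly.
#'
#' @param plan A `sample_plan` from [stratified_sample()].
#' @param path File path.
#' @return `write_sample_plan()` returns `path` invisibly;
#'   `read_sample_plan()` returns a `sample_plan` tibble.
#' @export
write_sample_plan <- function(plan, path) {
  stopifnot(inherits(plan, "sample_plan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", attr(plan, "seed")), con)
  writeLines(paste(c("category", "patient_id", "note_id"), collapse = "\t"), con)
  writeLines(paste(plan$category, plan$patient_id, plan$note_id, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_sample_plan
#' @export
read_sample_plan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seed_line <- grep("^# seed:", lines, value = TRUE)
  seed <- if (length(seed_line)) as.integer(sub("^# seed:\\s*", "", seed_line[1])) else NA_integer_
  plan <- readr::read_tsv(I(lines), comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  attr(plan, "seed") <- seed
  class(plan) <- c("sample_plan", class(plan))
  plan
}
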