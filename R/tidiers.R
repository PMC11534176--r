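#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for pipeline result objects
#'
#' broom-style accessors: `tidy()` returns the per-row detail of a result
#' (matches, per-patient sources, table rows, kept/removed matches) and
#' `glance()` a one-row summary.
#'
#' @param x A `corpus_search`, `fa_cohort`, `refinement_result`,
#'   `aggregate_table`, or `run_manifest`.
#' @param ... Unused; for generic consistency.
#' @return A tibble.
#' @name firearmtext-tidiers
NULL

#' @rdname firearmtext-tidiers
#' @method tidy corpus_search
#' @export
tidy.corpus_search <- function(x, ...) x$matches

#' @rdname firearmtext-tidiers
#' @method glance corpus_search
#' @export
glance.corpus_search <- function(x, ...) {
  tibble(n_notes = x$n_notes, n_notes_hit = x$n_notes_hit,
         n_patients = x$n_patients, n_patients_hit = x$n_patients_hit,
         n_matches = nrow(x$matches), n_empty_skipped = x$n_empty_skipped,
         mode = x$mode)
}

#' @rdname firearmtext-tidiers
#' @method tidy fa_cohort
#' @export
tidy.fa_cohort <- function(x, ...) x$cohort

#' @rdname firearmtext-tidiers
#' @method glance fa_cohort
#' @export
glance.fa_cohort <- function(x, ...) {
  wide <- setNames(as.list(x$mixture$prop), paste0("prop_", x$mixture$source))
  as_tibble(c(list(n_input = x$n_input, n_included = x$n_included), wide))
}

#' @rdname firearmtext-tidiers
#' @method tidy refinement_result
#' @export
tidy.refinement_result <- function(x, ...) {
  bind_rows(mutate(x$kept, kept = TRUE, reason = NA_character_),
            mutate(x$removed, kept = FALSE)) |>
    arrange(.data$note_id, .data$start, .data$end)
}

#' @rdname firearmtext-tidiers
#' @method glance refinement_result
#' @export
glance.refinement_result <- function(x, ...) {
  tibble(n_kept = nrow(x$kept), n_removed = nrow(x$removed))
}

#' @rdname firearmtext-tidiers
#' @method tidy aggregate_table
#' @export
tidy.aggregate_table <- function(x, ...) {
  as_tibble(as.data.frame(x, stringsAsFactors = FALSE))
}

#' @rdname firearmtext-tidiers
#' @method glance aggregate_table
#' @export
glance.aggregate_table <- function(x, ...) {
  tibble(total = attr(x, "total"), threshold = attr(x, "threshold"),
         n_rows = nrow(x), n_suppressed = sum(x$suppressed))
}

#' @rdname firearmtext-tidiers
#' @method glance run_manifest
#' @export
glance.run_manifest <- function(x, ...) as_tibble(x$funnel)
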