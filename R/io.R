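# Readers/writers for the record formats the pipeline consumes and emits:
# delimited tables (csv/tsv) or line-delimited JSON (jsonl/ndjson),
# chosen by file extension. Dates are ISO-8601 strings on disk.

read_records <- function(path, required, what) {
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character())),
    tsv = , txt = readr::read_tsv(path, show_col_types = FALSE,
                                  col_types = readr::cols(.default = readr::col_character())),
    jsonl = , ndjson = , json = as_tibble(jsonlite::stream_in(file(path), verbose = FALSE)),
    abort(sprintf("unsupported %s file extension: .%s (use csv, tsv, or jsonl)",
                  what, ext)))
  assert_columns(df, required, what)
  as_tibble(df)
}

write_records <- function(df, path) {
  ext <- tolower(tools::file_ext(path))
  df[] <- lapply(df, function(x) if (inherits(x, "Date")) as.character(x) else x)
  switch(ext,
    csv = readr::write_csv(df, path),
    tsv = , txt = readr::write_tsv(df, path),
    jsonl = , ndjson = , json = {
      con <- file(path, "w")
      on.exit(close(con))
      jsonlite::stream_out(as.data.frame(df), con, verbose = FALSE)
    },
    abort(sprintf("unsupported output extension: .%s", ext)))
  invisible(path)
}

#' Read and write clinical notes and structured event files
#'
#' Notes carry `note_id`, `patient_id`, `date`, `note_type`, `text`; ICD
#' events carry `patient_id`, `code`, `date`; SmartForm events carry
#' `patient_id`, `value`, `date`. Formats: `.csv`, `.tsv`, or
#' line-delimited JSON (`.jsonl`/`.ndjson`), selected by extension.
#'
#' @param path File path.
#' @param notes,events Data frame to write.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
read_notes <- function(path) {
  read_records(path, c("note_id", "patient_id", "date", "note_type", "text"),
               "notes")
}

#' @rdname read_notes
#' @export
write_notes <- function(notes, path) write_records(notes, path)

#' @rdname read_notes
#' @export
read_icd_events <- function(path) {
  read_records(path, c("patient_id", "code", "date"), "icd_events")
}

#' @rdname read_notes
#' @export
read_smartform_events <- function(path) {
  read_records(path, c("patient_id", "value", "date"), "smartform_events")
}

#' @rdname read_notes
#' @export
write_events <- function(events, path) write_records(events, path)
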