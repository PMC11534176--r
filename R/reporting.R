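#' Category distribution table with small-cell suppression
#'
#' Tabulates note context categories and prepares the publishable mirror:
#' integer percents (half-up rounding, so 13/90 prints as 14 and 16/90 as
#' 18) and suppression of any row whose count is strictly below the
#' threshold — suppressed rows display `"<10"` for the count and `"<5"`
#' for the percent, following the aggregate-reporting convention for
#' small cells. Exact counts and percents are retained internally and are
#' only written out when explicitly requested (see
#' [write_aggregate_table()]); suppression changes display strings, never
#' the underlying numbers.
#'
#' @param labels Character vector of note categories, or a data frame with
#'   a `category` column (e.g. the output of [categorize_notes()]).
#' @param threshold Suppress rows with `count < threshold` (default 10;
#'   a count exactly at the threshold is displayed).
#' @return A tibble of class `aggregate_table` with columns `label`,
#'   `count`, `percent` (exact), `percent_display` (rounded integer),
#'   `suppressed`, `display_count`, `display_percent`; attributes `total`
#'   and `threshold`. Rows cover the categories present in `labels`, in
#'   canonical order.
#' @export
#' @examples
#' labs <- rep(note_categories(), c(13, 36, 20, 16, 2, 2, 1))
#' category_table(labs)
category_table <- function(labels, threshold = 10) {
  if (is.data.frame(labels)) {
    assert_columns(labels, "category", "labels")
    labels <- labels$category
  }
  labels <- as.character(labels)
  if (length(labels) == 0) abort("`labels` must be non-empty.")
  unknown <- setdiff(unique(labels), note_categories())
  if (length(unknown) > 0) {
    abort(sprintf("unknown note category: %s", paste(unknown, collapse = ", ")))
  }
  total <- length(labels)
  tab <- tibble(label = factor(labels, levels = note_categories())) |>
    count(.data$label, name = "count") |>
    mutate(label = as.character(.data$label),
           percent = 100 * .data$count / total,
           percent_display = round_half_up(.data$percent, 0),
           suppressed = .data$count < threshold,
           display_count = if_else(.data$suppressed, "<10",
                                   as.character(.data$count)),
           display_percent = if_else(.data$suppressed, "<5",
                                     formatC(.data$percent_display,
                                             format = "d")))
  attr(tab, "total") <- total
  attr(tab, "threshold") <- threshold
  class(tab) <- c("aggregate_table", class(tab))
  tab
}

#' Indication-source composition table
#'
#' Percent of patients whose firearm-exposure indication came from an ICD
#' code, the SmartForm, or both — for the full population and, optionally,
#' a review sample, mirroring the published side-by-side composition.
#' Percents use one-decimal half-up rounding (61/90 prints as 67.8).
#'
#' @param population Character vector of sources in
#'   `c("icd", "smartform", "both")`, or a data frame with a `source`
#'   column (e.g. `build_cohort()$cohort`).
#' @param sample Optional second vector/data frame, same form.
#' @return A tibble of class `indication_table` with columns `group`,
#'   `source`, `count`, `percent`.
#' @export
#' @examples
#' indication_table(rep(c("icd", "smartform", "both"), c(61, 27, 2)))
indication_table <- function(population, sample = NULL) {
  one <- function(x, group) {
    if (is.data.frame(x)) {
      assert_columns(x, "source", "indication sources")
      x <- x$source
    }
    x <- as.character(x)
    if (length(x) == 0) abort("indication sources must be non-empty.")
    unknown <- setdiff(unique(x), c("icd", "smartform", "both"))
    if (length(unknown) > 0) {
      abort(sprintf("unknown indication source: %s", paste(unknown, collapse = ", ")))
    }
    tibble(source = factor(x, levels = c("icd", "smartform", "both"))) |>
      count(.data$source, name = "count") |>
      complete(source, fill = list(count = 0L)) |>
      mutate(group = group, source = as.character(.data$source),
             percent = round_half_up(100 * .data$count / length(x), 1)) |>
      select("group", "source", "count", "percent")
  }
  out <- one(population, "population")
  if (!is.null(sample)) out <- bind_rows(out, one(sample, "sample"))
  class(out) <- c("indication_table", class(out))
  out
}

#' @export
print.aggregate_table <- function(x, ...) {
  lab <- category_display_labels()[x$label]
  lab[is.na(lab)] <- x$label[is.na(lab)]
  w <- max(nchar(lab), nchar("Category"))
  cat(sprintf("%-*s  %3s  %3s\n", w, "Category", "%", "N"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-*s  %3s  %3s\n", w, lab[i],
                x$display_percent[i], x$display_count[i]))
  }
  cat(sprintf("%-*s  %3s  %3s\n", w, "Total", "100", attr(x, "total")))
  invisible(x)
}

#' @export
print.indication_table <- function(x, ...) {
  for (g in unique(x$group)) {
    sub <- x[x$group == g, ]
    cat(sprintf("%s (n = %d): %s\n", g, sum(sub$count),
                paste(sprintf("%s %.1f%%", sub$source, sub$percent),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write an aggregate table to delimited text
#'
#' By default only display-safe columns (suppressed counts shown as
#' `"<10"`, percents as `"<5"`) are written; `unsafe = TRUE` writes the
#' exact machine-readable counts and percents instead, for use inside a
#' protected environment.
#'
#' @param x An `aggregate_table` or `indication_table`.
#' @param path Output path (tab-delimited).
#' @param unsafe Write exact counts for suppressed rows (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_aggregate_table <- function(x, path, unsafe = FALSE) {
  if (inherits(x, "indication_table") || isTRUE(unsafe)) {
    out <- as_tibble(as.data.frame(x))
  } else {
    out <- tibble(label = x$label, count = x$display_count,
                  percent = x$display_percent)
  }
  readr::write_tsv(out, path)
  invisible(path)
}
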