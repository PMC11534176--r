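#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a category distribution table
#'
#' Bar chart of the category table; suppressed rows are drawn at the
#' suppression threshold with a `"<10"` label so small cells stay masked
#' in graphical output too.
#'
#' @param object An `aggregate_table` from [category_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aggregate_table
#' @export
autoplot.aggregate_table <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- tidy(object) |>
    mutate(shown = if_else(.data$suppressed, as.numeric(thr),
                           as.numeric(.data$count)),
           pretty = factor(category_display_labels()[.data$label],
                           levels = rev(unname(category_display_labels()))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pretty, y = .data$shown,
                                   fill = .data$suppressed)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_text(ggplot2::aes(label = .data$display_count), hjust = -0.15,
                       size = 3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "grey75"),
                               labels = c(`FALSE` = "reported", `TRUE` = "suppressed (<10)"),
                               name = NULL) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Notes",
                  title = sprintf("Note context categories (N = %d)",
                                  attr(object, "total"))) +
    ggplot2::theme_minimal()
}

#' Plot distinct patients per term category
#'
#' @param object A `corpus_search` from [search_corpus()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot corpus_search
#' @export
autoplot.corpus_search <- function(object, ...) {
  ggplot2::ggplot(object$patient_counts,
                  ggplot2::aes(x = .data$category, y = .data$n_patients)) +
    ggplot2::geom_col(width = 0.6, fill = "grey30") +
    ggplot2::labs(x = "Term category", y = "Distinct patients with >=1 hit",
                  title = sprintf("Keyword search: %d of %d patients with any hit",
                                  object$n_patients_hit, object$n_patients)) +
    ggplot2::theme_minimal()
}

#' Plot the pipeline funnel
#'
#' Patients (and notes) surviving each pipeline stage, from indication in
#' structured data through sampling.
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  f <- manifest$funnel
  df <- tibble(stage = factor(c("with indication", "with notes",
                                "with keyword hit", "sampled"),
                              levels = rev(c("with indication", "with notes",
                                             "with keyword hit", "sampled"))),
               n = c(f$n_patients_indicated, f$n_patients_with_notes,
                     f$n_patients_hit, f$n_sampled_patients))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(width = 0.6, fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.15, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Patients", title = "Surveillance funnel") +
    ggplot2::theme_minimal()
}
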