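#' Term and note category vocabularies
#'
#' The three lexicon term categories and the seven mutually exclusive
#' note context categories used throughout the package, in canonical order.
#'
#' @return A character vector.
#' @export
#' @examples
#' term_categories()
#' note_categories()
term_categories <- function() c("broad", "gun_only", "shooting")

#' @rdname term_categories
#' @export
note_categories <- function() {
  c("exposure", "assessment", "guidance_education", "treatment_care",
    "template_shot", "name_contains_term", "other")
}

# Display labels for aggregate-table mirrors.
category_display_labels <- function() {
  c(exposure           = "Exposure to firearms",
    assessment         = "Assessment",
    guidance_education = "Guidance and education",
    treatment_care     = "Treatment planning and/or care delivery",
    template_shot      = "Word \"shot\" in a template phrase",
    name_contains_term = "\"Gun\" in a name",
    other              = "Other")
}

#' Round half away from zero
#'
#' Printed percentages in published aggregate tables use conventional
#' half-up rounding (13/90 prints as 14%, 16/90 as 18%), which differs from
#' R's banker's rounding at .5 boundaries.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5)       # 3, where round(2.5) is 2
#' round_half_up(17.77, 1)  # 17.8
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Stop unless `df` has all of `cols`.
assert_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  what, paste0("`", missing, "`", collapse = ", ")))
  }
  invisible(df)
}

# Coerce to Date, erroring on values that fail to parse (rather than
# silently producing NA, which would corrupt window logic downstream).
as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
  bad <- !is.na(x) & is.na(d)
  if (any(bad)) {
    abort(sprintf("malformed %s value(s): %s (expected ISO-8601 YYYY-MM-DD)",
                  what, paste(unique(utils::head(x[bad], 3)), collapse = ", ")))
  }
  d
}
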