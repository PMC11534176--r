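#' Default firearm ICD-10-CM code prefixes
#'
#' The conventional external-cause families for firearm injury:
#' accidental discharge (W32-W34), intentional self-harm (X72-X74),
#' assault (X93-X95), undetermined intent (Y22-Y24), and legal
#' intervention involving firearm discharge (Y35.0). Matching is by
#' prefix, case- and dot-insensitive, so 7th-character encounter
#' extensions (e.g. "W34.00XA") qualify.
#'
#' @return Character vector of code prefixes.
#' @export
default_firearm_codes <- function() {
  c("W32", "W33", "W34", "X72", "X73", "X74",
    "X93", "X94", "X95", "Y22", "Y23", "Y24", "Y35.0")
}

#' Cohort configuration
#'
#' Date windows and value sets defining "indication of exposure to firearm
#' violence" in structured EHR data. The defaults reproduce the study
#' windows: ICD codes anywhere in the diagnosis or problem list from
#' 2012-01-01 through 2022-12-31, and a SmartForm "exposure to gun
#' violence" value of recent/historical from the form's 2022-02-01
#' go-live through 2022-12-31.
#'
#' @param icd_window Length-2 vector (start, end) of ISO dates for ICD events.
#' @param smartform_window Length-2 vector (start, end) for SmartForm events.
#' @param firearm_code_set ICD-10-CM code prefixes counted as firearm injury.
#' @param qualifying_smartform_values SmartForm values counted as exposure
#'   (compared case-insensitively after trimming).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(icd_window = c("2012-01-01", "2022-12-31"),
                          smartform_window = c("2022-02-01", "2022-12-31"),
                          firearm_code_set = default_firearm_codes(),
                          qualifying_smartform_values = c("recent", "historical")) {
  icd_window <- as_date_strict(icd_window, "icd_window")
  smartform_window <- as_date_strict(smartform_window, "smartform_window")
  for (w in list(icd_window, smartform_window)) {
    if (length(w) != 2L || anyNA(w) || w[1] > w[2]) {
      abort("windows must be length-2 (start, end) with start <= end.")
    }
  }
  structure(list(icd_window = icd_window,
                 smartform_window = smartform_window,
                 firearm_code_set = toupper(gsub(".", "", firearm_code_set, fixed = TRUE)),
                 qualifying_smartform_values = tolower(trimws(qualifying_smartform_values))),
            class = "cohort_config")
}

# Dot- and case-insensitive prefix test of codes against the configured set.
code_is_firearm <- function(code, prefixes) {
  norm <- toupper(gsub(".", "", code, fixed = TRUE))
  Reduce(`|`, lapply(prefixes, function(p) startsWith(norm, p)),
         init = rep(FALSE, length(norm)))
}

#' Classify each patient's indication source
#'
#' Derives, for every patient appearing in either event table, whether
#' their firearm-exposure indication comes from an ICD code, the
#' SmartForm, both, or neither. The ICD criterion is at least one event
#' whose code starts with a configured firearm prefix and whose date lies
#' in the ICD window; the SmartForm criterion is at least one event with a
#' qualifying value in the SmartForm window.
#'
#' @param icd_events Data frame with columns `patient_id`, `code`, `date`.
#' @param smartform_events Data frame with columns `patient_id`, `value`,
#'   `date`.
#' @param config A [cohort_config()].
#' @return A tibble (`patient_id`, `source`) with `source` in
#'   `c("icd", "smartform", "both", "none")`, one row per patient.
#' @export
#' @examples
#' icd <- data.frame(patient_id = "P1", code = "W34.00XA", date = "2015-06-01")
#' sf <- data.frame(patient_id = "P2", value = "recent", date = "2022-03-01")
#' classify_indication(icd, sf, cohort_config())
classify_indication <- function(icd_events, smartform_events,
                                config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  assert_columns(icd_events, c("patient_id", "code", "date"), "icd_events")
  assert_columns(smartform_events, c("patient_id", "value", "date"), "smartform_events")
  if (any(!nzchar(trimws(c(icd_events$patient_id, smartform_events$patient_id))))) {
    abort("empty patient_id in event records.")
  }

  icd <- as_tibble(icd_events)
  icd$date <- as_date_strict(icd$date, "icd event date")
  sf <- as_tibble(smartform_events)
  sf$date <- as_date_strict(sf$date, "smartform event date")

  icd_ok <- icd |>
    filter(code_is_firearm(.data$code, config$firearm_code_set),
           .data$date >= config$icd_window[1],
           .data$date <= config$icd_window[2]) |>
    distinct(.data$patient_id) |>
    mutate(icd_hit = TRUE)
  sf_ok <- sf |>
    filter(tolower(trimws(.data$value)) %in% config$qualifying_smartform_values,
           .data$date >= config$smartform_window[1],
           .data$date <= config$smartform_window[2]) |>
    distinct(.data$patient_id) |>
    mutate(sf_hit = TRUE)

  tibble(patient_id = sort(unique(c(icd$patient_id, sf$patient_id)))) |>
    left_join(icd_ok, by = "patient_id") |>
    left_join(sf_ok, by = "patient_id") |>
    mutate(icd_hit = !is.na(.data$icd_hit),
           sf_hit = !is.na(.data$sf_hit),
           source = case_when(.data$icd_hit & .data$sf_hit ~ "both",
                              .data$icd_hit ~ "icd",
                              .data$sf_hit ~ "smartform",
                              TRUE ~ "none")) |>
    select("patient_id", "source")
}

#' Build the exposure-indication cohort
#'
#' Applies [classify_indication()] and keeps patients with any indication
#' (`source != "none"`), returning the cohort together with the mixture of
#' indication sources among included patients.
#'
#' @inheritParams classify_indication
#' @return A list of class `fa_cohort`: `cohort` (tibble `patient_id`,
#'   `source`, sources restricted to icd/smartform/both), `mixture` (tibble
#'   `source`, `n`, `prop`; proportions over included patients sum to 1),
#'   `n_input`, `n_included`.
#' @export
build_cohort <- function(icd_events, smartform_events, config = cohort_config()) {
  all_sources <- classify_indication(icd_events, smartform_events, config)
  cohort <- filter(all_sources, .data$source != "none")
  mixture <- cohort |>
    count(source = factor(.data$source, levels = c("icd", "smartform", "both"))) |>
    complete(source, fill = list(n = 0L)) |>
    mutate(source = as.character(.data$source),
           prop = if (nrow(cohort) > 0) .data$n / nrow(cohort) else NA_real_)
  structure(list(cohort = cohort, mixture = mixture,
                 n_input = nrow(all_sources), n_included = nrow(cohort),
                 config = config),
            class = "fa_cohort")
}

#' @export
print.fa_cohort <- function(x, ...) {
  cat(sprintf("<firearm exposure cohort: %d of %d patients with indication>\n",
              x$n_included, x$n_input))
  print(x$mixture, ...)
  invisible(x)
}
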