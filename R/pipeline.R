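#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: input tables (or file
#' paths, or `NULL` to synthesize them), the lexicon and rule set (or
#' paths, or `NULL` for the shipped defaults), cohort windows, match mode,
#' sample size per term category, seeds, and the suppression threshold.
#' All randomness in a run flows from the two named seeds (`seed_generate`
#' for synthesis, `seed_sample` for note sampling), which are echoed in
#' the run manifest.
#'
#' @param notes,icd_events,smartform_events Data frames, file paths, or
#'   `NULL` (synthesize via `generator`).
#' @param lexicon A `fa_lexicon`, a lexicon file path, or `NULL` for
#'   [default_lexicon()].
#' @param rules A `rule_set`, a YAML path, or `NULL` for [default_rules()].
#' @param cohort A [cohort_config()].
#' @param generator A [generator_config()] used when inputs are `NULL`.
#' @param mode,window Match mode and context window (see [find_matches()]).
#' @param n_per_category Notes to sample per term category.
#' @param seed_sample,seed_generate Integer seeds.
#' @param suppression_threshold Small-cell threshold for reporting.
#' @param out_dir Optional directory; when set, stage outputs and the
#'   manifest are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(notes = NULL, icd_events = NULL, smartform_events = NULL,
                       lexicon = NULL, rules = NULL,
                       cohort = cohort_config(),
                       generator = generator_config(n_patients = 500),
                       mode = c("substring", "word_boundary"), window = 60,
                       n_per_category = 30,
                       seed_sample = 1L, seed_generate = generator$seed,
                       suppression_threshold = 10,
                       out_dir = NULL) {
  structure(list(notes = notes, icd_events = icd_events,
                 smartform_events = smartform_events,
                 lexicon = lexicon, rules = rules,
                 cohort = cohort, generator = generator,
                 mode = match.arg(mode), window = window,
                 n_per_category = n_per_category,
                 seed_sample = as.integer(seed_sample),
                 seed_generate = as.integer(seed_generate),
                 suppression_threshold = suppression_threshold,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments; `notes`,
#' `icd_events`, `smartform_events`, `lexicon` and `rules` are file paths,
#' and `cohort`/`generator` are nested key maps passed to their
#' constructors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("notes", "icd_events", "smartform_events", "lexicon",
                        "rules", "mode", "window", "n_per_category",
                        "seed_sample", "seed_generate",
                        "suppression_threshold", "out_dir"))]
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_config, y$cohort)
  if (!is.null(y$generator)) args$generator <- do.call(generator_config, y$generator)
  do.call(run_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline aborted at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "fa_pipeline_error")
  })
}

#' Run the end-to-end surveillance pipeline
#'
#' Executes the stage order of the chart-review workflow — cohort
#' derivation from structured data, restriction to cohort patients'
#' notes, lexicon search, stratified sampling, rule-based categorization
#' with refinement, and suppressed aggregate reporting — and returns a
#' manifest recording the funnel of counts at every stage (patients with
#' indication, patients with notes, notes searched, distinct patients
#' with a hit, sampled notes) together with the seeds and the config
#' echo, so a run can be reproduced exactly. Any stage failure aborts
#' with the stage name and cause.
#'
#' @param config A [run_config()] (or a YAML path).
#' @return A list of class `run_manifest` with elements `funnel`,
#'   `cohort_mixture`, `indication_table`, `sample_plan`, `labels`,
#'   `category_table`, `refinement_summary`, `seeds`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  lex <- run_stage("lexicon", {
    x <- config$lexicon
    if (is.null(x)) default_lexicon()
    else if (is.character(x)) read_lexicon(x)
    else x
  })
  rules <- run_stage("rules", {
    x <- config$rules
    if (is.null(x)) default_rules()
    else if (is.character(x)) read_rules(x)
    else x
  })

  inputs <- run_stage("inputs", {
    if (is.null(config$notes)) {
      gen <- config$generator
      gen$seed <- config$seed_generate
      pop <- generate_population(gen)
      list(notes = pop$notes, icd = pop$icd_events, sf = pop$smartform_events)
    } else {
      list(
        notes = if (is.character(config$notes)) read_notes(config$notes) else as_tibble(config$notes),
        icd = if (is.character(config$icd_events)) read_icd_events(config$icd_events) else as_tibble(config$icd_events),
        sf = if (is.character(config$smartform_events)) read_smartform_events(config$smartform_events) else as_tibble(config$smartform_events))
    }
  })

  cohort <- run_stage("cohort", build_cohort(inputs$icd, inputs$sf, config$cohort))

  cohort_notes <- run_stage("notes", {
    semi_join(inputs$notes, cohort$cohort, by = "patient_id")
  })

  search <- run_stage("search", {
    search_corpus(cohort_notes, lex, mode = config$mode, window = config$window)
  })

  plan <- run_stage("sampling", {
    stratified_sample(search, n_per_category = config$n_per_category,
                      seed = config$seed_sample)
  })

  labels <- run_stage("categorize", {
    sampled_matches <- semi_join(search$matches, plan, by = "note_id")
    categorize_notes(sampled_matches, rules)
  })
  refinement <- run_stage("refine", {
    apply_refinement_filters(semi_join(search$matches, plan, by = "note_id"),
                             rules)
  })

  report <- run_stage("report", {
    sample_sources <- cohort$cohort |>
      semi_join(distinct(plan, .data$patient_id), by = "patient_id")
    list(indication = indication_table(cohort$cohort, sample_sources),
         categories = category_table(labels,
                                     threshold = config$suppression_threshold))
  })

  manifest <- structure(list(
    funnel = list(
      n_patients_input = n_distinct(c(inputs$icd$patient_id,
                                      inputs$sf$patient_id,
                                      inputs$notes$patient_id)),
      n_patients_indicated = cohort$n_included,
      n_patients_with_notes = n_distinct(cohort_notes$patient_id),
      n_notes_searched = nrow(cohort_notes),
      n_patients_hit = search$n_patients_hit,
      n_sampled_notes = nrow(plan),
      n_sampled_patients = n_distinct(plan$patient_id)),
    cohort_mixture = cohort$mixture,
    indication_table = report$indication,
    sample_plan = plan,
    labels = labels,
    category_table = report$categories,
    refinement_summary = if (nrow(refinement$removed) > 0)
      count(refinement$removed, .data$reason) else
        tibble(reason = character(), n = integer()),
    seeds = list(generate = config$seed_generate, sample = config$seed_sample),
    config = config), class = "run_manifest")

  if (!is.null(config$out_dir)) write_manifest(manifest, config$out_dir)
  manifest
}

# Persist stage outputs as plain text under `dir`.
write_manifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sample_plan(manifest$sample_plan, file.path(dir, "sample_plan.tsv"))
  readr::write_tsv(manifest$labels, file.path(dir, "labels.tsv"))
  write_aggregate_table(manifest$category_table,
                        file.path(dir, "category_table.tsv"))
  write_aggregate_table(manifest$indication_table,
                        file.path(dir, "indication_table.tsv"))
  jsonlite::write_json(
    list(funnel = manifest$funnel, seeds = manifest$seeds),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<pipeline run manifest>\n")
  f <- x$funnel
  cat(sprintf(paste0("  funnel: %d patients -> %d with indication -> %d with notes",
                     " -> %d notes searched -> %d patients with hits -> %d sampled notes\n"),
              f$n_patients_input, f$n_patients_indicated, f$n_patients_with_notes,
              f$n_notes_searched, f$n_patients_hit, f$n_sampled_notes))
  cat(sprintf("  seeds: generate %d, sample %d\n", x$seeds$generate, x$seeds$sample))
  print(x$category_table)
  invisible(x)
}
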