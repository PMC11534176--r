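#' Context-categorization rule sets
#'
#' A rule set drives [categorize_matches()] and
#' [apply_refinement_filters()]. It holds, per note category, a list of
#' lowercase cue phrases tested by containment against each match's context
#' window; a list of known EHR template phrases (SmartPhrases) such as
#' `"[Shot for Birth Control: Care Instructions.]"`; regex cues naming
#' injectable medications (used by the "shot"-as-injection refinement
#' filter); the order in which categories are tried for a single match
#' (`match_order`, first firing cue wins, fallback `other`); and the
#' precedence used to resolve a multi-match note to one category
#' (`note_precedence`, exposure first for surveillance sensitivity). Both
#' orders must be permutations of the seven categories and are
#' user-editable via the YAML rules file.
#'
#' @param cues Named list: category -> character vector of cue phrases.
#' @param template_phrases Character vector of template phrases (stored
#'   lowercase).
#' @param injectable_cues Character vector of lowercase regex patterns.
#' @param match_order,note_precedence Permutations of [note_categories()].
#' @param version Free-text label.
#' @return A list of class `rule_set`.
#' @seealso [default_rules()], [read_rules()]
#' @export
rule_set <- function(cues, template_phrases = character(),
                     injectable_cues = character(),
                     match_order, note_precedence,
                     version = "custom") {
  cats <- note_categories()
  for (ord in list(match_order, note_precedence)) {
    if (!setequal(ord, cats) || length(ord) != length(cats)) {
      abort("match_order and note_precedence must each be a permutation of the seven note categories.")
    }
  }
  unknown <- setdiff(names(cues), cats)
  if (length(unknown) > 0) {
    abort(sprintf("cue list for unknown category: %s", paste(unknown, collapse = ", ")))
  }
  cues <- lapply(setNames(cats, cats), function(cat) tolower(cues[[cat]] %||% character()))
  structure(list(cues = cues,
                 template_phrases = tolower(template_phrases),
                 injectable_cues = tolower(injectable_cues),
                 match_order = match_order,
                 note_precedence = note_precedence,
                 version = version),
            class = "rule_set")
}

#' Default rule set
#'
#' The rule set shipped with the package, seeded from the example phrases
#' of each of the seven context categories (exposure, assessment, guidance
#' and education, treatment planning/care delivery, template "shot",
#' keyword inside a name, other).
#'
#' @return A `rule_set`.
#' @export
default_rules <- function() {
  read_rules(system.file("extdata", "default_rules.yml",
                         package = "firearmtext", mustWork = TRUE))
}

#' Read / write a rule set as YAML
#'
#' @param path Path to a YAML rules file with keys `cues`,
#'   `template_phrases`, `injectable_cues`, `match_order`,
#'   `note_precedence`, `version`.
#' @param rules A `rule_set`.
#' @return `read_rules()` returns a `rule_set`; `write_rules()` returns
#'   `path` invisibly.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) abort(sprintf("rules file not found: %s", path))
  y <- yaml::read_yaml(path)
  rule_set(cues = lapply(y$cues, as.character),
           template_phrases = as.character(y$template_phrases %||% character()),
           injectable_cues = as.character(y$injectable_cues %||% character()),
           match_order = as.character(y$match_order),
           note_precedence = as.character(y$note_precedence),
           version = y$version %||% basename(path))
}

#' @rdname read_rules
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  yaml::write_yaml(list(version = rules$version,
                        match_order = rules$match_order,
                        note_precedence = rules$note_precedence,
                        cues = rules$cues,
                        template_phrases = rules$template_phrases,
                        injectable_cues = rules$injectable_cues),
                   path)
  invisible(path)
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule set '%s': %d cue phrases, %d template phrases>\n",
              x$version, sum(lengths(x$cues)), length(x$template_phrases)))
  invisible(x)
}
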