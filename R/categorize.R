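# --- match-level categorization ---------------------------------------------

# Maximal run of word characters containing positions s..e (1-based,
# inclusive) of `text`; used to recover the token a match sits in.
token_at <- function(text, s, e) {
  chars <- stringi::stri_sub(text, seq_len(stringi::stri_length(text)),
                             length = 1)
  isw <- stringi::stri_detect_regex(chars, "[\\p{L}\\p{N}_]")
  a <- s
  while (a > 1 && isw[a - 1]) a <- a - 1
  b <- e
  while (b < length(chars) && isw[b + 1]) b <- b + 1
  paste(chars[a:b], collapse = "")
}

# TRUE when the match sits strictly inside a token whose original casing
# begins uppercase and which is longer than the term itself ("Gunther" for
# term "gun" qualifies; "Gunshot" for term "gunshot" does not).
is_proper_name_match <- function(token, surface) {
  stringi::stri_detect_regex(token, "^\\p{Lu}") &
    stringi::stri_length(token) > stringi::stri_length(surface)
}

any_cue <- function(ctx_lower, cues) {
  length(cues) > 0 && any(stringi::stri_detect_fixed(ctx_lower, cues))
}

# TRUE when some occurrence of some cue overlaps span [rel_s, rel_e]
# (1-based, inclusive) within the context. Used for the first, local pass
# of cue evaluation: a cue that contains the matched term itself speaks
# about that occurrence, not about another firearm term elsewhere in the
# window.
any_cue_overlapping <- function(ctx_lower, cues, rel_s, rel_e) {
  if (length(cues) == 0) return(FALSE)
  for (cue in cues) {
    loc <- stringi::stri_locate_all_fixed(ctx_lower, cue)[[1]]
    if (is.na(loc[1, 1])) next
    if (any(loc[, 1] <= rel_e & loc[, 2] >= rel_s)) return(TRUE)
  }
  FALSE
}

#' Assign a context category to each term match
#'
#' Labels every match with one of the seven context categories by testing
#' the rule set's cue phrases (lowercase containment) against the match's
#' context window, in the rule set's `match_order`. Structural rules:
#' `name_contains_term` fires when the match lies inside a capitalized
#' token longer than the term (a surname like "Gunther"); `template_shot`
#' fires when the context contains a configured template phrase. Cues are
#' evaluated in two passes: first only cues whose occurrence overlaps the
#' matched term may fire (a "no guns" cue elsewhere in the window cannot
#' relabel a "hears gunshots" match), then plain containment anywhere in
#' the window as fallback. The first category whose rule fires wins; a
#' match firing no rule is `other`.
#'
#' @param matches A match tibble from [find_matches()] /
#'   [search_corpus()]`$matches` (needs `surface`, `context`, `start`,
#'   `end`, `context_start`).
#' @param rules A [rule_set()]; defaults to [default_rules()].
#' @return `matches` with an added `match_category` column.
#' @export
#' @examples
#' m <- find_matches("Cortisone shot in left knee.", default_lexicon())
#' categorize_matches(m)$match_category
categorize_matches <- function(matches, rules = default_rules()) {
  stopifnot(inherits(rules, "rule_set"))
  assert_columns(matches, c("surface", "context", "start", "end", "context_start"),
                 "matches")
  n <- nrow(matches)
  if (n == 0) return(mutate(matches, match_category = character(0)))
  ctx_lower <- stringi::stri_trans_tolower(matches$context)
  rel_s <- matches$start - matches$context_start + 1L
  rel_e <- matches$end - matches$context_start
  tokens <- map_chr(seq_len(n), function(i)
    token_at(matches$context[i], rel_s[i], rel_e[i]))
  proper <- is_proper_name_match(tokens, matches$surface)

  # Two passes over the rule order. First, only cues whose occurrence
  # overlaps the matched term may fire (so "no guns" elsewhere in the
  # window cannot relabel a "hears gunshots" match); if nothing fires,
  # plain containment anywhere in the context window is the fallback.
  # Structural rules (proper-name token, template phrase) participate in
  # the first pass: they are intrinsically about this occurrence.
  label_one <- function(i) {
    for (cat in rules$match_order) {
      hit <- switch(cat,
        name_contains_term = proper[i] ||
          any_cue_overlapping(ctx_lower[i], rules$cues$name_contains_term,
                              rel_s[i], rel_e[i]),
        template_shot = any_cue(ctx_lower[i], rules$template_phrases) ||
          any_cue(ctx_lower[i], rules$cues$template_shot),
        any_cue_overlapping(ctx_lower[i], rules$cues[[cat]],
                            rel_s[i], rel_e[i]))
      if (hit) return(cat)
    }
    for (cat in rules$match_order) {
      hit <- switch(cat,
        name_contains_term = any_cue(ctx_lower[i], rules$cues$name_contains_term),
        any_cue(ctx_lower[i], rules$cues[[cat]]))
      if (hit) return(cat)
    }
    "other"
  }
  mutate(matches, match_category = map_chr(seq_len(n), label_one))
}

# --- note-level categorization ----------------------------------------------

#' Resolve matches to one mutually exclusive category per note
#'
#' Each note receives the highest-precedence category (rule set
#' `note_precedence`; by default exposure > assessment > guidance/education
#' > treatment/care > template "shot" > name > other) among its match-level
#' labels. Exposure outranks everything so that a note with any exposure
#' evidence is an exposure note, the sensitive choice for surveillance.
#' Deterministic: no randomness anywhere in categorization.
#'
#' @param matches A match tibble covering one or more notes (a
#'   `match_category` column is added via [categorize_matches()] if
#'   absent).
#' @inheritParams categorize_matches
#' @return A tibble (`note_id`, `category`), one row per note present in
#'   `matches`.
#' @export
categorize_notes <- function(matches, rules = default_rules()) {
  if (inherits(matches, "corpus_search")) matches <- matches$matches
  if (!"match_category" %in% names(matches)) {
    matches <- categorize_matches(matches, rules)
  }
  if (nrow(matches) == 0) {
    return(tibble(note_id = character(), category = character()))
  }
  prec <- rules$note_precedence
  matches |>
    mutate(.rank = match(.data$match_category, prec)) |>
    group_by(.data$note_id) |>
    summarise(category = prec[min(.data$.rank)], .groups = "drop")
}

#' Categorize a single note's text
#'
#' Convenience wrapper: runs [find_matches()] then [categorize_notes()] on
#' one string. Errors if the note contains no lexicon match, since the
#' categories describe the context of a keyword hit.
#'
#' @param text A single note text.
#' @inheritParams find_matches
#' @inheritParams categorize_matches
#' @return A single category string.
#' @export
#' @examples
#' categorize_note("Gunshot wound of the right lower leg.")
#' categorize_note("Remove guns from the home.")
categorize_note <- function(text, lexicon = default_lexicon(),
                            rules = default_rules(),
                            mode = c("substring", "word_boundary"),
                            window = 60) {
  m <- find_matches(text, lexicon, mode = match.arg(mode), window = window)
  if (nrow(m) == 0) abort("note has no lexicon matches; nothing to categorize.")
  categorize_notes(m, rules)$category[[1]]
}

# --- refinement filters ------------------------------------------------------

#' Remove keyword matches that do not reflect firearm violence
#'
#' Applies the refinement filters identified during chart review, each
#' tagged with a removal reason (tested in this order; the first that
#' applies wins):
#' \describe{
#'   \item{template_phrase}{the context contains a configured EHR template
#'     phrase, e.g. `"[Shot for Birth Control: Care Instructions.]"`}
#'   \item{proper_name}{the match lies inside a capitalized token longer
#'     than the term ("Gunther" for "gun")}
#'   \item{injection_shot}{a "shot" term whose context names an injectable
#'     (immunization, vaccine, hepatitis, DMPA, cortisone, birth control,
#'     flu)}
#'   \item{pain_shooting}{a "shooting" term whose context contains "pain"
#'     and no other firearm-term match}
#' }
#' All other matches are kept. Kept and removed partition the input.
#'
#' @param matches A match tibble (or `corpus_search`); rows must carry
#'   `note_id`, `surface`, `context`, `start`, `end`, `context_start`.
#' @inheritParams categorize_matches
#' @return A list of class `refinement_result`: `kept` (match tibble) and
#'   `removed` (match tibble with a `reason` column).
#' @export
#' @examples
#' m <- find_matches("Shot of Hepatitis A.", default_lexicon())
#' apply_refinement_filters(m)$removed$reason
apply_refinement_filters <- function(matches, rules = default_rules()) {
  if (inherits(matches, "corpus_search")) matches <- matches$matches
  stopifnot(inherits(rules, "rule_set"))
  assert_columns(matches,
                 c("note_id", "surface", "context", "start", "end", "context_start"),
                 "matches")
  n <- nrow(matches)
  if (n == 0) {
    res <- list(kept = matches, removed = mutate(matches, reason = character(0)))
    class(res) <- "refinement_result"
    return(res)
  }
  ctx_lower <- stringi::stri_trans_tolower(matches$context)
  rel_s <- matches$start - matches$context_start + 1L
  rel_e <- matches$end - matches$context_start
  tokens <- map_chr(seq_len(n), function(i)
    token_at(matches$context[i], rel_s[i], rel_e[i]))
  proper <- is_proper_name_match(tokens, matches$surface)
  is_template <- map_lgl_safe(ctx_lower, function(ctx)
    any_cue(ctx, rules$template_phrases))
  has_injectable <- map_lgl_safe(ctx_lower, function(ctx)
    length(rules$injectable_cues) > 0 &&
      any(stringi::stri_detect_regex(ctx, rules$injectable_cues)))
  has_pain <- stringi::stri_detect_fixed(ctx_lower, "pain")

  # Another firearm-term match (different span, not itself a "shooting"
  # term) whose span intersects this match's context window counts as
  # "other reference to firearm terms" for the pain rule.
  ctx_end <- matches$context_start + stringi::stri_length(matches$context)
  other_firearm <- vapply(seq_len(n), function(i) {
    same <- matches$note_id == matches$note_id[i]
    cand <- same & (matches$start != matches$start[i] |
                      matches$end != matches$end[i]) &
      !matches$surface %in% c("shot", "shooting") &
      matches$start < ctx_end[i] & matches$end > matches$context_start[i]
    any(cand)
  }, logical(1))

  reason <- rep(NA_character_, n)
  reason[is_template] <- "template_phrase"
  shotish <- stringi::stri_detect_fixed(matches$surface, "shot")
  reason[is.na(reason) & proper] <- "proper_name"
  reason[is.na(reason) & shotish & has_injectable] <- "injection_shot"
  reason[is.na(reason) & matches$surface == "shooting" & has_pain &
           !other_firearm] <- "pain_shooting"

  res <- list(kept = matches[is.na(reason), , drop = FALSE],
              removed = mutate(matches[!is.na(reason), , drop = FALSE],
                               reason = reason[!is.na(reason)]))
  class(res) <- "refinement_result"
  res
}

map_lgl_safe <- function(x, f) vapply(x, f, logical(1), USE.NAMES = FALSE)

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("<refinement: %d matches kept, %d removed", nrow(x$kept), nrow(x$removed)))
  if (nrow(x$removed) > 0) {
    tab <- table(x$removed$reason)
    cat(" (", paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "),
        ")", sep = "")
  }
  cat(">\n")
  invisible(x)
}
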