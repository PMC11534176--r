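#' Build a firearm term lexicon
#'
#' A lexicon is a tibble of lowercase search terms, each assigned to one of
#' three term categories: `broad` firearm-violence terms (e.g. "firearm"),
#' `gun_only` terms (e.g. "gun"), and `shooting` verbs (e.g. "shot").
#' Terms are matched case-insensitively as literal substrings (or at word
#' boundaries) by [find_matches()].
#'
#' @param surface Character vector of terms; stored lowercase and trimmed.
#' @param category Character vector of term categories, recycled if length 1;
#'   each must be one of [term_categories()].
#' @param version_label Free-text label recorded on the lexicon.
#' @return A tibble of class `fa_lexicon` with columns `surface`, `category`.
#' @seealso [read_lexicon()], [default_lexicon()], [find_matches()]
#' @export
#' @examples
#' lexicon(c("firearm", "gun", "shot"), c("broad", "gun_only", "shooting"))
lexicon <- function(surface, category, version_label = "custom") {
  if (length(category) == 1L) category <- rep(category, length(surface))
  if (length(surface) != length(category)) {
    abort("`surface` and `category` must have the same length.")
  }
  surface <- tolower(trimws(as.character(surface)))
  category <- trimws(as.character(category))
  if (length(surface) == 0) abort("empty lexicon: at least one term is required.")
  if (any(!nzchar(surface))) abort("lexicon terms must be non-empty after trimming.")
  unknown <- setdiff(unique(category), term_categories())
  if (length(unknown) > 0) {
    abort(sprintf("unknown term category: %s (must be one of %s)",
                  paste(unknown, collapse = ", "),
                  paste(term_categories(), collapse = ", ")))
  }
  key <- paste(surface, category, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- surface[duplicated(key)]
    abort(sprintf("duplicate lexicon row(s): %s", paste(unique(dup), collapse = ", ")))
  }
  out <- tibble(surface = surface, category = category)
  attr(out, "version_label") <- version_label
  class(out) <- c("fa_lexicon", class(out))
  out
}

#' Read a lexicon from a delimited file
#'
#' Expects two columns (term, category), tab- or comma-delimited, with
#' category one of [term_categories()]. Lines starting with `#` and blank
#' lines are ignored; an optional `term<delim>category` header row is
#' skipped. A warning is raised if any of the three categories ends up
#' empty, since downstream sampling expects all three strata.
#'
#' @param path Path to the lexicon file.
#' @param version_label Label recorded on the lexicon; defaults to the
#'   file name.
#' @return A `fa_lexicon` tibble.
#' @export
read_lexicon <- function(path, version_label = basename(path)) {
  if (!file.exists(path)) abort(sprintf("lexicon file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(sprintf("empty lexicon file: %s", path))
  parts <- stringi::stri_split_regex(lines, "[\t,]", n = 2L)
  bad <- map_int(parts, length) != 2L
  if (any(bad)) {
    abort(sprintf("malformed lexicon line(s) (need term<TAB or ,>category): %s",
                  paste(utils::head(lines[bad], 3), collapse = "; ")))
  }
  term <- map_chr(parts, 1)
  cat <- trimws(map_chr(parts, 2))
  if (tolower(term[1]) == "term" && tolower(cat[1]) == "category") {
    term <- term[-1]; cat <- cat[-1]
    if (length(term) == 0) abort(sprintf("empty lexicon file: %s", path))
  }
  lex <- lexicon(term, cat, version_label = version_label)
  empty <- setdiff(term_categories(), unique(lex$category))
  if (length(empty) > 0) {
    warning(sprintf("lexicon has no terms in category: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  lex
}

#' The default firearm lexicon
#'
#' A small built-in lexicon of exemplar firearm terms covering all three
#' term categories: firearm and GSW (broad), gun and gunpoint (gun-only),
#' shot, shooting and gunshot (shooting verbs). Site-specific keyword lists
#' should be supplied via [read_lexicon()]; this default exists so the
#' pipeline runs out of the box and so substring behavior (e.g. "gun"
#' matching inside "Gunther" or "nailgun") is exercised.
#'
#' @return A `fa_lexicon` tibble of 7 terms.
#' @export
#' @examples
#' default_lexicon()
default_lexicon <- function() {
  path <- system.file("extdata", "default_lexicon.tsv", package = "firearmtext",
                      mustWork = TRUE)
  read_lexicon(path, version_label = "default-exemplars")
}

#' Find lexicon term matches in text
#'
#' Scans `text` for every lexicon term, case-insensitively, and returns one
#' row per occurrence with 0-based character offsets (`end` exclusive) into
#' the original text. In `substring` mode a term matches anywhere, including
#' inside a longer token ("gun" inside "gunpoint" or "Gunther"); in
#' `word_boundary` mode the characters adjacent to the match must not be
#' word characters. Overlapping matches from different terms are all
#' reported, and self-overlapping occurrences of a single term are found.
#'
#' @param text A single character string (may be empty).
#' @param lexicon A `fa_lexicon`, e.g. [default_lexicon()].
#' @param mode `"substring"` (default) or `"word_boundary"`. Substring is
#'   the default because surveillance keyword search favors sensitivity;
#'   downstream refinement filters handle the false positives it admits.
#' @param window Number of context characters captured either side of each
#'   match (default 60).
#' @param note_id Optional identifier recorded on each match.
#' @return A tibble sorted by (`start`, `end`) with columns `note_id`,
#'   `start`, `end`, `matched_text`, `surface`, `category`, `context`,
#'   `context_start` (0-based offset of the context window in the text).
#' @export
#' @examples
#' find_matches("Pt. was robbed at gunpoint.", default_lexicon())
find_matches <- function(text, lexicon = default_lexicon(),
                         mode = c("substring", "word_boundary"),
                         window = 60, note_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) text <- ""
  locate_matches(texts = text, note_ids = note_id, patient_ids = NA_character_,
                 lexicon = lexicon, mode = mode, window = window)
}

# Vectorized matching engine shared by find_matches() and search_corpus().
# One stri_locate_all_fixed() call per term over the whole text vector.
locate_matches <- function(texts, note_ids, patient_ids, lexicon, mode, window) {
  stopifnot(inherits(lexicon, "fa_lexicon"))
  if (window < 0) abort("`window` must be non-negative.")
  texts <- ifelse(is.na(texts), "", texts)
  nch <- stringi::stri_length(texts)
  opts <- stringi::stri_opts_fixed(case_insensitive = TRUE, overlap = TRUE)

  pieces <- vector("list", nrow(lexicon))
  for (i in seq_len(nrow(lexicon))) {
    surf <- lexicon$surface[i]
    loc <- stringi::stri_locate_all_fixed(texts, surf, opts_fixed = opts)
    n_per <- map_int(loc, function(m) if (is.na(m[1, 1])) 0L else nrow(m))
    if (sum(n_per) == 0L) next
    idx <- rep.int(seq_along(texts), n_per)
    m <- do.call(rbind, loc[n_per > 0L])
    s1 <- unname(m[, 1]); e1 <- unname(m[, 2])  # 1-based inclusive
    if (mode == "word_boundary") {
      before <- stringi::stri_sub(texts[idx], pmax(s1 - 1L, 1L), s1 - 1L)
      after <- stringi::stri_sub(texts[idx], e1 + 1L, e1 + 1L)
      ok <- !stringi::stri_detect_regex(before, "[\\p{L}\\p{N}_]") &
            !stringi::stri_detect_regex(after, "[\\p{L}\\p{N}_]")
      if (!any(ok)) next
      idx <- idx[ok]; s1 <- s1[ok]; e1 <- e1[ok]
    }
    cs <- pmax(s1 - window, 1L)
    ce <- pmin(e1 + window, nch[idx])
    pieces[[i]] <- tibble(
      note_id = note_ids[idx],
      patient_id = patient_ids[idx],
      start = s1 - 1L,
      end = e1,
      matched_text = stringi::stri_sub(texts[idx], s1, e1),
      surface = surf,
      category = lexicon$category[i],
      context = stringi::stri_sub(texts[idx], cs, ce),
      context_start = cs - 1L
    )
  }
  out <- list_rbind(c(list(empty_match_tbl()), pieces))
  arrange(out, .data$note_id, .data$start, .data$end, .data$surface)
}

empty_match_tbl <- function() {
  tibble(note_id = character(), patient_id = character(),
         start = integer(), end = integer(),
         matched_text = character(), surface = character(),
         category = character(), context = character(),
         context_start = integer())
}

#' @export
print.fa_lexicon <- function(x, ...) {
  cat(sprintf("<firearm lexicon '%s': %d terms (%s)>\n",
              attr(x, "version_label") %||% "?", nrow(x),
              paste(sprintf("%s %d", names(table(x$category)),
                            as.integer(table(x$category))), collapse = ", ")))
  NextMethod()
}
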