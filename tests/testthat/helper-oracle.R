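# Independent brute-force matcher: scan every start position of every term
# against the lowercased text. Deliberately naive; used as the oracle for
# the production matcher.
naive_find_matches <- function(text, lex) {
  lt <- tolower(text)
  n <- nchar(lt)
  rows <- list()
  for (i in seq_len(nrow(lex))) {
    surf <- lex$surface[i]
    L <- nchar(surf)
    if (L == 0 || L > n) next
    for (s in seq_len(n - L + 1)) {
      if (substr(lt, s, s + L - 1) == surf) {
        rows[[length(rows) + 1]] <- data.frame(
          start = s - 1L, end = s + L - 1L,
          surface = surf, category = lex$category[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(),
               surface = character(), category = character(),
               stringsAsFactors = FALSE)
  out[order(out$start, out$end, out$surface), , drop = FALSE]
}

# Random text over a vocabulary rich in term fragments, so self-overlaps,
# case variation and substring containment all occur.
rand_text <- function(n_tokens) {
  pool <- c("gun", "GUN", "Gun", "shot", "Shot", "sho", "gunshot", "gsw",
            "GSW", "firearm", "un", "t", "a", "xx", " ", " ", ".", "nailgun",
            "Gunther", "shooting", "oo")
  paste(sample(pool, n_tokens, replace = TRUE), collapse = "")
}

rand_lexicon <- function(max_terms = 10) {
  pool <- c("gun", "shot", "gu", "un", "sho", "gunshot", "t", "gsw",
            "firearm", "oo", "shooting", "a", "ther")
  surfaces <- sample(pool, sample.int(max_terms, 1))
  surfaces <- unique(surfaces)
  firearmtext::lexicon(surfaces,
                       sample(firearmtext::term_categories(),
                              length(surfaces), replace = TRUE))
}

match_key <- function(m) {
  m <- as.data.frame(m)[, c("start", "end", "surface", "category")]
  m <- m[order(m$start, m$end, m$surface), , drop = FALSE]
  rownames(m) <- NULL
  m
}
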