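test_that("lexicon files load, validate, and reject bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "firearm\tbroad", "gun\tgun_only", "shot\tshooting",
               "shooting\tshooting", "gunshot\tshooting"), path)
  lex <- read_lexicon(path)
  expect_s3_class(lex, "fa_lexicon")
  expect_equal(nrow(lex), 5)
  expect_setequal(unique(lex$category), term_categories())

  writeLines(c("gun,gun_only", "gun,gun_only"), path)
  expect_error(read_lexicon(path), "duplicate")
  writeLines("pistol,weapons", path)
  expect_error(read_lexicon(path), "unknown term category")
  writeLines(c("# nothing here"), path)
  expect_error(read_lexicon(path), "empty lexicon")
  expect_error(read_lexicon(file.path(tempdir(), "nope.tsv")), "not found")

  # terms stored lowercase/trimmed; same surface may sit in two categories
  lex2 <- lexicon(c(" GUN ", "gun"), c("gun_only", "broad"))
  expect_equal(lex2$surface, c("gun", "gun"))
  expect_error(lexicon(c("gun", "GUN"), "gun_only"), "duplicate")
})

test_that("substring matches report exact offsets, including inside longer tokens", {
  lex <- lexicon("gun", "gun_only")
  expect_equal(nrow(find_matches("", lex)), 0)

  m <- find_matches("Pt. was robbed at gunpoint.", lex)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 18L)
  expect_equal(m$end, 21L)
  expect_equal(m$matched_text, "gun")

  m2 <- find_matches("Provider name includes Gunther", lex)
  expect_equal(nrow(m2), 1)
  expect_equal(tolower(m2$matched_text), "gun")
  # word-boundary mode drops in-token matches
  expect_equal(nrow(find_matches("Provider name includes Gunther", lex,
                                 mode = "word_boundary")), 0)
  expect_equal(nrow(find_matches("a gun here", lex, mode = "word_boundary")), 1)
})

test_that("matcher agrees with the brute-force oracle on random inputs", {
  withr::local_seed(42)
  for (i in 1:60) {
    txt <- rand_text(sample.int(40, 1))
    lex <- rand_lexicon()
    got <- find_matches(txt, lex)
    expect_equal(match_key(got), match_key(naive_find_matches(txt, lex)))
    # offsets index the original text
    if (nrow(got) > 0) {
      expect_true(all(got$start >= 0 & got$start < got$end &
                        got$end <= nchar(txt)))
      expect_equal(tolower(got$matched_text), got$surface)
    }
  }
})

test_that("matching is case-insensitive and monotone in the lexicon", {
  withr::local_seed(7)
  for (i in 1:20) {
    txt <- rand_text(25)
    lex <- rand_lexicon()
    up <- find_matches(toupper(txt), lex)
    base <- find_matches(txt, lex)
    expect_equal(match_key(up), match_key(base))
    # adding a term never removes matches
    extra <- lexicon(c(lex$surface, "zzz"), c(lex$category, "broad"))
    grown <- find_matches(txt, extra)
    expect_true(nrow(grown) >= nrow(base))
    expect_equal(match_key(grown[grown$surface != "zzz", ]), match_key(base))
  }
})

test_that("context windows clip to the note and record their origin", {
  lex <- lexicon("gun", "gun_only")
  txt <- paste0(strrep("x", 100), "gun", strrep("y", 100))
  m <- find_matches(txt, lex, window = 10)
  expect_equal(m$context, paste0(strrep("x", 10), "gun", strrep("y", 10)))
  expect_equal(m$context_start, 90L)
  m2 <- find_matches("gun", lex, window = 60)
  expect_equal(m2$context, "gun")
  expect_equal(m2$context_start, 0L)
})
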