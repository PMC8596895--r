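fx <- fixture_paper_example()

test_that("find_replaceable returns non-event lexicon words only", {
  idx <- find_replaceable(fx$sentence, fx$lexicon)
  expect_equal(fx$sentence$tokens[idx], c("has", "worked", "up"))

  # every token inside an event span: nothing replaceable
  all_event <- labeled_sentence(c("barium", "enema"), c("B-test", "E-test"))
  expect_length(find_replaceable(all_event, fx$lexicon), 0)

  # tokens absent from the lexicon
  none <- labeled_sentence(c("alpha", "beta"), c("O", "O"))
  expect_length(find_replaceable(none, fx$lexicon), 0)

  # digit-bearing and punctuation tokens are never replaceable
  lex <- lexicon(list(`09/97` = list(synonyms = "x"),
                      `.` = list(synonyms = "y")))
  digits <- labeled_sentence(c("09/97", "."), c("O", "O"))
  expect_length(find_replaceable(digits, lex), 0)
})

test_that("select_replacement follows the relation priority order", {
  # worked: no synonyms/antonyms, hypernym "set" wins
  expect_equal(select_replacement("worked", fx$lexicon), "set")
  # up: antonym only; excluded => no replacement
  expect_equal(select_replacement("up", fx$lexicon), "down")
  expect_null(select_replacement("up", fx$lexicon, exclude_antonyms = TRUE))
  expect_null(select_replacement("nothere", fx$lexicon))
  # synonyms beat all later relations; first element of the stored list wins
  lex <- lexicon(list(w = list(synonyms = c("s1", "s2"), hypernyms = "h")))
  expect_equal(select_replacement("w", lex), "s1")
  # capitalization mirrors the source word
  expect_equal(select_replacement("W", lex), "S1")
})

test_that("augment_sentence reproduces the worked replacement example", {
  all_mode <- augment_sentence(fx$sentence, fx$lexicon, "all")
  expect_length(all_mode, 1)
  expect_equal(paste(all_mode[[1]]$tokens, collapse = " "),
               "She have been set down with barium enema 09/97 .")

  no_ant <- augment_sentence(fx$sentence, fx$lexicon, "all_no_ant")
  expect_length(no_ant, 1)
  expect_equal(paste(no_ant[[1]]$tokens, collapse = " "),
               "She have been set up with barium enema 09/97 .")

  one <- augment_sentence(fx$sentence, fx$lexicon, "one_no_ant")
  expect_length(one, 2)
  expect_equal(paste(one[[1]]$tokens, collapse = " "),
               "She have been worked up with barium enema 09/97 .")
  expect_equal(paste(one[[2]]$tokens, collapse = " "),
               "She has been set up with barium enema 09/97 .")

  # all outputs keep the source tag sequence
  for (s in c(all_mode, no_ant, one)) {
    expect_equal(s$tags, fx$sentence$tags)
  }
})

test_that("augment_corpus appends generated sentences after the originals", {
  out <- augment_corpus(list(fx$sentence), fx$lexicon, "one_no_ant")
  expect_length(out, 3) # 1 original + 2 generated
  expect_equal(out[[1]], fx$sentence)

  # empty lexicon leaves the corpus unchanged
  expect_equal(augment_corpus(list(fx$sentence), lexicon(), "all"),
               list(fx$sentence))
  expect_error(augment_corpus(list(fx$sentence), fx$lexicon, "all",
                              sample_fraction = 0), "sample_fraction")
})

test_that("subsampling the generated pool is deterministic given the seed", {
  corpus <- generate_corpus(synth_config(n_sentences = 40, seed = 2))
  lex <- generate_lexicon(attr(corpus, "filler_vocab"), seed = 3)
  a <- augment_corpus(corpus, lex, "one_no_ant", sample_fraction = 0.5,
                      seed = 9)
  b <- augment_corpus(corpus, lex, "one_no_ant", sample_fraction = 0.5,
                      seed = 9)
  expect_equal(a, b)
  full <- augment_corpus(corpus, lex, "one_no_ant")
  expect_equal(length(a) - length(corpus),
               round(0.5 * (length(full) - length(corpus))))
})

test_that("augmentation preserves tags and token counts on random corpora", {
  set.seed(23)
  corpus <- generate_corpus(synth_config(n_sentences = 60, seed = 14))
  lex <- generate_lexicon(attr(corpus, "filler_vocab"), seed = 15)
  for (mode in c("all", "all_no_ant", "one_no_ant")) {
    for (sent in corpus[1:30]) {
      for (gen in augment_sentence(sent, lex, mode)) {
        expect_identical(gen$tags, sent$tags)
        expect_length(gen$tokens, length(sent$tokens))
      }
    }
  }
  # size bounds: "all" at most doubles; one_no_ant adds one per replacement
  out_all <- augment_corpus(corpus, lex, "all")
  expect_lte(length(out_all), 2 * length(corpus))
})

test_that("all_no_ant replacements are never antonym-sourced", {
  set.seed(31)
  corpus <- generate_corpus(synth_config(n_sentences = 50, seed = 16))
  lex <- generate_lexicon(attr(corpus, "filler_vocab"), seed = 17)
  for (sent in corpus) {
    for (gen in augment_sentence(sent, lex, "all_no_ant")) {
      changed <- which(gen$tokens != sent$tokens)
      for (i in changed) {
        # every changed token must be the antonym-free selection for its source
        expect_equal(gen$tokens[i],
                     select_replacement(sent$tokens[i], lex,
                                        exclude_antonyms = TRUE))
        expect_false(gen$tokens[i] %in%
                       clinevent:::lexicon_lookup(lex, sent$tokens[i])$antonyms)
      }
    }
  }
})

test_that("lexicon JSON round-trips through read/write", {
  path <- withr::local_tempfile(fileext = ".json")
  write_lexicon(fx$lexicon, path)
  back <- read_lexicon(path)
  expect_equal(back$entries, fx$lexicon$entries)
})
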