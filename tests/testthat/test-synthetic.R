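test_that("generated corpora are schema-valid and deterministic", {
  cfg <- synth_config(n_sentences = 100, seed = 42)
  corpus <- generate_corpus(cfg)
  expect_length(corpus, 100)
  for (s in corpus) {
    expect_true(isTRUE(clinevent:::check_bioes(s$tags)))
    expect_length(s$tags, length(s$tokens))
  }
  expect_equal(generate_corpus(cfg), corpus)
})

test_that("signal strength 1 stamps every event token with its type affix", {
  corpus <- generate_corpus(synth_config(n_sentences = 80, signal = 1.0,
                                         seed = 7))
  markers <- clinevent:::type_markers
  for (s in corpus) {
    ev <- which(s$tags != "O")
    for (i in ev) {
      ty <- substring(s$tags[i], 3)
      expect_true(endsWith(s$tokens[i], strrep(markers[[ty]], 3)))
    }
    # filler tokens never contain a marker letter
    for (i in setdiff(seq_along(s$tokens), ev)) {
      expect_false(grepl(paste0("[", paste(markers, collapse = ""), "]"),
                         s$tokens[i]))
    }
  }
})

test_that("empirical type proportions track the configured proportions", {
  corpus <- generate_corpus(synth_config(n_sentences = 3000, seed = 19))
  spans <- unlist(lapply(corpus, function(s) {
    vapply(decode_tags(s$tags, "strict"), `[[`, character(1), "type")
  }))
  shares <- table(spans) / length(spans)
  # uniform config: every share within +/- 3 percentage points of 1/6
  expect_true(all(abs(shares - 1 / 6) < 0.03))
})

test_that("infeasible configurations error", {
  expect_error(synth_config(max_len = 2), "counts too small|infeasible")
  expect_error(synth_config(event_len_range = c(1, 20)), "infeasible")
  expect_error(synth_config(proportions = c(problem = 1)), "named by")
})

test_that("generated lexica only key and draw from filler words", {
  corpus <- generate_corpus(synth_config(n_sentences = 50, seed = 3))
  vocab <- attr(corpus, "filler_vocab")
  lex <- generate_lexicon(vocab, seed = 4)
  expect_true(all(names(lex$entries) %in% vocab))
  cands <- unlist(lapply(lex$entries, unlist))
  expect_true(all(cands %in% vocab))
  expect_equal(generate_lexicon(vocab, seed = 4), lex)
})

test_that("augmenting a generated corpus grows it without touching tags", {
  corpus <- generate_corpus(synth_config(n_sentences = 40, seed = 8))
  lex <- generate_lexicon(attr(corpus, "filler_vocab"), seed = 9)
  out <- augment_corpus(corpus, lex, "all")
  expect_gt(length(out), length(corpus))
  for (i in seq_along(corpus)) {
    expect_identical(out[[i]]$tags, corpus[[i]]$tags)
  }
})

test_that("generated corpora round-trip through the CoNLL format", {
  corpus <- generate_corpus(synth_config(n_sentences = 30, seed = 5))
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(corpus, path)
  back <- read_conll(path)
  attr(corpus, "filler_vocab") <- NULL
  expect_equal(back, corpus)
})

test_that("the packaged fixture is stable and matches its documentation", {
  fx1 <- fixture_paper_example()
  fx2 <- fixture_paper_example()
  expect_identical(fx1, fx2)
  expect_length(fx1$sentence$tokens, 10)
  e <- fx1$lexicon$entries[["worked"]]
  expect_equal(e$hypernyms, "set")
  expect_equal(e$hyponyms, "cut")
  expect_equal(e$related_words, "put")
  expect_length(e$synonyms, 0)
  expect_length(e$antonyms, 0)
})
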