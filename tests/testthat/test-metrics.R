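sp <- function(...) list(...)

test_that("strict matching requires exact boundaries and type", {
  g <- list(sp(event_span(1, 4, "problem")))
  p_exact <- list(sp(event_span(1, 4, "problem")))
  r <- strict_prf(g, p_exact)
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))

  p_off <- list(sp(event_span(1, 3, "problem")))
  r <- strict_prf(g, p_off)
  expect_equal(c(r$precision, r$recall, r$f1), c(0, 0, 0))

  # direct arithmetic: TP=3, FP=1, FN=2
  g <- list(sp(event_span(0, 1, "test"), event_span(2, 3, "test"),
               event_span(4, 5, "test"), event_span(6, 7, "test"),
               event_span(8, 9, "test")))
  p <- list(sp(event_span(0, 1, "test"), event_span(2, 3, "test"),
               event_span(4, 5, "test"), event_span(5, 6, "test")))
  r <- strict_prf(g, p)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$f1, 2 / 3)
  expect_error(strict_prf(list(sp()), list(sp(), sp())), "sentences")
})

test_that("lenient matching counts overlapping spans regardless of type", {
  g <- list(sp(event_span(1, 4, "problem")))
  p <- list(sp(event_span(2, 5, "test")))
  r <- lenient_span_prf(g, p)
  expect_equal(r$f1, 1)

  r <- lenient_span_prf(list(sp(event_span(1, 4, "problem"))),
                        list(sp(event_span(5, 7, "problem"))))
  expect_equal(r$f1, 0)

  # one prediction overlapping two golds matches only one of them
  g <- list(sp(event_span(0, 2, "test"), event_span(3, 5, "test")))
  p <- list(sp(event_span(1, 4, "test")))
  r <- lenient_span_prf(g, p)
  expect_equal(r$tp, 1); expect_equal(r$fp, 0); expect_equal(r$fn, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 2 / 3)
  # the tie (equal 1-token overlaps) resolves to the earlier gold span
  expect_equal(r$pairs[[1]]$gold$start, 0L)
})

test_that("type accuracy is the agreement fraction over matched pairs", {
  pairs <- list(list(pred = event_span(0, 1, "test"),
                     gold = event_span(0, 1, "test")),
                list(pred = event_span(2, 3, "problem"),
                     gold = event_span(2, 3, "test")))
  expect_equal(as.numeric(type_accuracy(pairs)), 0.5)
  expect_equal(as.numeric(type_accuracy(pairs[1])), 1)
  expect_warning(z <- type_accuracy(list()), "undefined")
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "undefined"))
})

test_that("predicting gold exactly yields all three metrics equal to 1", {
  set.seed(53)
  corpus <- generate_corpus(synth_config(n_sentences = 25, seed = 6))
  rep <- evaluate_corpus(corpus, corpus)
  expect_equal(rep$strict$f1, 1)
  expect_equal(rep$lenient$f1, 1)
  expect_equal(rep$type_accuracy, 1)
})

test_that("strict F1 never exceeds lenient span F1", {
  set.seed(59)
  for (rep_i in 1:20) {
    n <- 10
    gold <- lapply(1:n, function(i) rand_spans(sample(4:10, 1)))
    pred <- lapply(1:n, function(i) rand_spans(sample(4:10, 1)))
    s <- strict_prf(gold, pred)
    l <- lenient_span_prf(gold, pred)
    expect_lte(s$f1, l$f1 + 1e-12)
  }
})

test_that("metrics are invariant under sentence reordering and additive", {
  set.seed(61)
  gold <- lapply(1:8, function(i) rand_spans(8))
  pred <- lapply(1:8, function(i) rand_spans(8))
  perm <- sample(8)
  a <- strict_prf(gold, pred)
  b <- strict_prf(gold[perm], pred[perm])
  expect_equal(a, b)
  # micro counts add over shards
  s1 <- strict_prf(gold[1:4], pred[1:4])
  s2 <- strict_prf(gold[5:8], pred[5:8])
  expect_equal(a$tp, s1$tp + s2$tp)
  expect_equal(a$fp, s1$fp + s2$fp)
  expect_equal(a$fn, s1$fn + s2$fn)
})

test_that("evaluate_corpus reports per-type strict F1", {
  g <- list(labeled_sentence(c("a", "b", "c"),
                             c("S-test", "O", "S-problem")))
  p <- list(labeled_sentence(c("a", "b", "c"),
                             c("S-test", "O", "O")))
  rep <- evaluate_corpus(g, p)
  pt <- rep$per_type
  expect_equal(pt$f1[pt$type == "test"], 1)
  expect_equal(pt$f1[pt$type == "problem"], 0)
  expect_equal(rep$strict$tp, 1)
  expect_equal(rep$strict$fn, 1)
})
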