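test_that("sequence scores match the termwise definition", {
  # single position, two labels, emissions [1, 0], no transitions
  sc <- matrix(c(1, 0), 1, 2)
  crf <- crf_params(2)
  expect_equal(crf_sequence_score(sc, 1, crf), 1)
  expect_equal(crf_sequence_score(sc, 2, crf), 0)

  # all parameters zero: every sequence scores 0
  sc0 <- matrix(0, 3, 4)
  crf0 <- crf_params(4)
  expect_equal(crf_sequence_score(sc0, c(2, 3, 1), crf0), 0)

  # random instance vs an explicit termwise loop
  set.seed(13)
  l <- 3; d_f <- 4
  sc <- matrix(rnorm(l * d_f), l, d_f)
  crf <- crf_params(d_f)
  crf$trans <- matrix(rnorm(d_f^2), d_f, d_f)
  crf$start <- rnorm(d_f); crf$stop <- rnorm(d_f)
  y <- c(2, 4, 1)
  manual <- crf$start[y[1]] + sc[1, y[1]] +
    crf$trans[y[1], y[2]] + sc[2, y[2]] +
    crf$trans[y[2], y[3]] + sc[3, y[3]] + crf$stop[y[3]]
  expect_equal(crf_sequence_score(sc, y, crf), manual)
  expect_error(crf_sequence_score(sc, c(1, 2), crf), "length")
  expect_error(crf_sequence_score(sc, c(1, 2, 9), crf), "out of range")
})

test_that("forward-algorithm log partition matches explicit sums", {
  # l = 1, emissions [1, 0]: log(e^1 + e^0)
  sc <- matrix(c(1, 0), 1, 2)
  expect_equal(crf_log_partition(sc, crf_params(2)), log(exp(1) + 1))
  # all-zero parameters: logZ = l * log(d_f)
  expect_equal(crf_log_partition(matrix(0, 3, 5), crf_params(5)), log(125))
})

test_that("log partition, Viterbi and total probability agree with enumeration", {
  set.seed(17)
  for (rep in 1:50) {
    l <- sample(1:5, 1); d_f <- sample(2:4, 1)
    sc <- matrix(rnorm(l * d_f), l, d_f)
    crf <- crf_params(d_f)
    crf$trans <- matrix(rnorm(d_f^2), d_f, d_f)
    crf$start <- rnorm(d_f); crf$stop <- rnorm(d_f)
    all_scores <- crf_enumerate(sc, crf)
    lz <- logsumexp_vec(all_scores)
    expect_equal(crf_log_partition(sc, crf), lz, tolerance = 1e-8)
    y <- viterbi_decode(sc, crf)
    expect_equal(crf_sequence_score(sc, y, crf), max(all_scores),
                 tolerance = 1e-10)
    expect_equal(sum(exp(all_scores - lz)), 1, tolerance = 1e-8)
  }
})

test_that("Viterbi decodes factorized and tied cases deterministically", {
  set.seed(19)
  # no transitions: per-position argmax
  sc <- matrix(rnorm(12), 4, 3)
  expect_equal(viterbi_decode(sc, crf_params(3)), apply(sc, 1, which.max))
  # all-zero parameters: the tie rule picks label 1 everywhere
  expect_equal(viterbi_decode(matrix(0, 3, 4), crf_params(4)), rep(1L, 3))
})

test_that("Viterbi beats random sequences", {
  set.seed(29)
  for (rep in 1:10) {
    l <- sample(2:8, 1); d_f <- sample(2:6, 1)
    sc <- matrix(rnorm(l * d_f), l, d_f)
    crf <- crf_params(d_f)
    crf$trans <- matrix(rnorm(d_f^2), d_f, d_f)
    best <- crf_sequence_score(sc, viterbi_decode(sc, crf), crf)
    for (k in 1:100) {
      y <- sample.int(d_f, l, replace = TRUE)
      expect_gte(best, crf_sequence_score(sc, y, crf))
    }
  }
})

test_that("the negative log-likelihood behaves like a proper loss", {
  # uniform model: per-sentence loss is l * log(d_f)
  sc <- matrix(0, 2, 3)
  expect_equal(crf_nll(list(sc), list(c(1, 2)), crf_params(3)), 2 * log(3))
  # non-negative on random instances
  set.seed(37)
  for (rep in 1:10) {
    l <- sample(1:5, 1); d_f <- 3
    sc <- matrix(rnorm(l * d_f), l, d_f)
    crf <- crf_params(d_f); crf$trans <- matrix(rnorm(9), 3, 3)
    y <- sample.int(d_f, l, replace = TRUE)
    expect_gte(crf_nll(list(sc), list(y), crf), 0)
  }
})

test_that("NLL gradients match finite differences", {
  set.seed(43)
  l <- 4; d_f <- 3
  sc <- matrix(rnorm(l * d_f), l, d_f)
  crf <- crf_params(d_f)
  crf$trans <- matrix(rnorm(d_f^2), d_f, d_f)
  crf$start <- rnorm(d_f); crf$stop <- rnorm(d_f)
  y <- c(1, 3, 2, 2)
  bw <- clinevent:::crf_nll_backward(sc, y, crf)
  eps <- 1e-6
  f0 <- crf_nll(list(sc), list(y), crf)
  sc2 <- sc; sc2[2, 3] <- sc2[2, 3] + eps
  expect_equal((crf_nll(list(sc2), list(y), crf) - f0) / eps,
               bw$dscores[2, 3], tolerance = 1e-4)
  crf2 <- crf; crf2$trans[1, 3] <- crf2$trans[1, 3] + eps
  expect_equal((crf_nll(list(sc), list(y), crf2) - f0) / eps,
               bw$grads$trans[1, 3], tolerance = 1e-4)
  crf2 <- crf; crf2$start[1] <- crf2$start[1] + eps
  expect_equal((crf_nll(list(sc), list(y), crf2) - f0) / eps,
               bw$grads$start[1], tolerance = 1e-4)
})
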