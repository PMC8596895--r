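test_that("relative position embeddings have the sinusoidal structure", {
  expect_equal(rel_pos_embedding(0, 4), c(0, 1, 0, 1))
  expect_equal(rel_pos_embedding(1, 2), c(sin(1), cos(1)))
  expect_error(rel_pos_embedding(1, 3), "even")
  # direction awareness: sines odd, cosines even in the offset
  for (k in c(1, 3, 7)) {
    pos <- rel_pos_embedding(k, 6)
    neg <- rel_pos_embedding(-k, 6)
    sines <- seq(1, 6, by = 2); coss <- seq(2, 6, by = 2)
    expect_equal(neg[sines], -pos[sines])
    expect_equal(neg[coss], pos[coss])
  }
  tab <- rel_pos_table(5, 4)
  expect_equal(dim(tab$R), c(9, 4))
  expect_equal(tab$R[5, ], c(0, 1, 0, 1)) # offset 0 row
})

test_that("attention scores match the per-pair scalar oracle", {
  set.seed(41)
  for (rep in 1:20) {
    hd <- valid_head_dims[[sample.int(length(valid_head_dims), 1)]]
    heads <- hd["heads"]; d <- hd["d"]
    L <- sample(2:8, 1)
    H <- matrix(rnorm(L * d), L, d)
    p <- tener_params(d, heads, d_ff = 8, seed = rep)
    h <- sample(seq_len(heads), 1)
    A <- attention_scores(H, p, h)
    Aor <- attention_score_oracle(H, p, h)
    expect_lt(max(abs(A - Aor)) / max(abs(Aor)), 1e-6)
  }
})

test_that("zeroed query/bias parameters give uniform attention", {
  L <- 5; d <- 4
  p <- tener_params(d, 2, d_ff = 6, seed = 1)
  for (h in 1:2) {
    p$W_q[[h]][] <- 0; p$u[[h]][] <- 0; p$v[[h]][] <- 0
  }
  H <- matrix(rnorm(L * d), L, d)
  A <- attention_scores(H, p, 1)
  expect_equal(A, matrix(0, L, L))
  W <- clinevent:::row_softmax(A)
  expect_equal(W, matrix(1 / L, L, L))
})

test_that("softmax rows sum to one and masked positions get zero weight", {
  set.seed(5)
  L <- 6; d <- 4
  H <- matrix(rnorm(L * d), L, d)
  p <- tener_params(d, 2, d_ff = 6, seed = 2)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  A <- attention_scores(H, p, 1, mask = mask)
  W <- clinevent:::row_softmax(A)
  expect_equal(rowSums(W), rep(1, L))
  expect_equal(W[, 5:6], matrix(0, L, 2))
  # masked keys contribute nothing: perturbing them leaves unmasked rows as-is
  out1 <- tener_layer(H, p, norm = FALSE, mask = mask)
  H2 <- H; H2[5, ] <- H2[5, ] + 100
  out2 <- tener_layer(H2, p, norm = FALSE, mask = mask)
  expect_equal(out1[1:4, ], out2[1:4, ])
})

test_that("single-token input reduces to the value/FFN path", {
  d <- 4
  p <- tener_params(d, 1, d_ff = 6, seed = 3)
  H <- matrix(rnorm(d), 1, d)
  W <- clinevent:::row_softmax(attention_scores(H, p, 1))
  expect_equal(W, matrix(1, 1, 1))
  att <- H %*% p$W_v[[1]]
  expected <- clinevent:::ffn_forward(att, p$W1, p$b1, p$W2, p$b2)$out
  expect_equal(tener_layer(H, p, norm = FALSE), expected)
})

test_that("zero input with zero biases yields zero output when norm is off", {
  d <- 6
  p <- tener_params(d, 3, d_ff = 8, seed = 4)
  p$b1[] <- 0; p$b2[] <- 0
  out <- tener_layer(matrix(0, 4, d), p, norm = FALSE)
  expect_equal(out, matrix(0, 4, d))
})

test_that("the layer is position-dependent, not permutation-equivariant", {
  set.seed(9)
  d <- 4
  p <- tener_params(d, 1, d_ff = 6, seed = 5)
  H <- matrix(rnorm(3 * d), 3, d)
  out <- tener_layer(H, p, norm = FALSE)
  perm <- c(3, 1, 2)
  out_perm <- tener_layer(H[perm, ], p, norm = FALSE)
  # if the layer ignored positions, out_perm would equal out[perm, ]
  expect_gt(max(abs(out_perm - out[perm, ])), 1e-6)
})

test_that("direction awareness: +k and -k offsets score differently", {
  d <- 4
  p <- tener_params(d, 1, d_ff = 6, seed = 6)
  L <- 5
  H <- matrix(rnorm(L * d), L, d)
  A <- attention_scores(H, p, 1)
  k <- 2; t <- 3
  Rk <- rel_pos_embedding(k, d); Rmk <- rel_pos_embedding(-k, d)
  witness <- sum(p$v[[1]] * (Rk - Rmk)) +
    sum((H[t, ] %*% p$W_q[[1]]) * (Rk - Rmk))
  if (abs(witness) > 1e-8) {
    expect_false(isTRUE(all.equal(A[t, t - k], A[t, t + k])))
  }
})

test_that("a stack of layers preserves the L x d shape", {
  d <- 8
  H <- matrix(rnorm(5 * d), 5, d)
  for (k in 1:2) {
    p <- tener_params(d, 2, d_ff = 12, seed = k)
    H <- tener_layer(H, p, norm = TRUE)
    expect_equal(dim(H), c(5L, d))
  }
  expect_error(tener_layer(matrix(0, 2, 6), tener_params(8, 2, 8)), "width")
})
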