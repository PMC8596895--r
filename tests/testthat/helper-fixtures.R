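# Shared test fixtures, all built in code.

toy_schema <- tag_schema()

# random non-overlapping span set for a sentence of length n
rand_spans <- function(n, schema = toy_schema, max_spans = 3) {
  spans <- list()
  occupied <- rep(FALSE, n)
  for (k in seq_len(sample(0:max_spans, 1))) {
    le <- sample(1:min(3, n), 1)
    starts <- which(vapply(seq_len(n - le + 1), function(s) {
      !any(occupied[s:(s + le - 1)])
    }, logical(1)))
    if (length(starts) == 0) next
    s <- starts[sample.int(length(starts), 1)]
    occupied[s:(s + le - 1)] <- TRUE
    spans[[length(spans) + 1]] <- event_span(s - 1, s + le - 1,
                                             sample(schema$types, 1))
  }
  spans
}

span_df <- function(spans) {
  if (length(spans) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      type = character(0)))
  }
  df <- data.frame(start = vapply(spans, `[[`, integer(1), "start"),
                   end = vapply(spans, `[[`, integer(1), "end"),
                   type = vapply(spans, `[[`, character(1), "type"))
  df[order(df$start), , drop = FALSE]
}

expect_same_spans <- function(a, b) {
  da <- span_df(a); db <- span_df(b)
  rownames(da) <- NULL; rownames(db) <- NULL
  expect_equal(da, db)
}

# valid (heads, d) pairs for the attention layer (per-head width must be even)
valid_head_dims <- local({
  out <- list()
  for (heads in 1:3) {
    for (d in seq(2, 12, by = 2)) {
      if (d %% heads == 0 && (d %/% heads) %% 2 == 0) {
        out[[length(out) + 1]] <- c(heads = heads, d = d)
      }
    }
  }
  out
})

# tiny model + corpus for smoke tests
tiny_model_setup <- function(n = 10, seed = 5) {
  corpus <- generate_corpus(synth_config(n_sentences = n, vocab_size = 12,
                                         max_len = 8, seed = seed))
  cfg <- ced_config(char = char_encoder_config(cd = 6, heads = 3, cd_ff = 8,
                                               layers = 1, wl = 10),
                    wd = 8, d_model = 8, layers = 1, heads = 2, d_ff = 12)
  model <- ced_model(corpus, cfg, seed = seed + 1)
  list(corpus = corpus, model = model, cfg = cfg)
}

# scalar per-pair oracle for the relative-position attention score
attention_score_oracle <- function(H, params, head) {
  L <- nrow(H)
  dk <- ncol(params$W_q[[head]])
  Q <- H %*% params$W_q[[head]]
  K <- H[, ((head - 1) * dk + 1):(head * dk), drop = FALSE]
  A <- matrix(0, L, L)
  for (t in seq_len(L)) {
    for (j in seq_len(L)) {
      R <- rel_pos_embedding(t - j, dk)
      A[t, j] <- sum(Q[t, ] * K[j, ]) + sum(Q[t, ] * R) +
        sum(params$u[[head]] * K[j, ]) + sum(params$v[[head]] * R)
    }
  }
  A
}

# brute-force CRF oracle: enumerate all label sequences
crf_enumerate <- function(scores, crf) {
  l <- nrow(scores); d_f <- ncol(scores)
  ys <- as.matrix(expand.grid(rep(list(seq_len(d_f)), l)))
  vapply(seq_len(nrow(ys)), function(i) {
    crf_sequence_score(scores, ys[i, ], crf)
  }, numeric(1))
}

logsumexp_vec <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
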