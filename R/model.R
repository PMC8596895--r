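# Full tagger: character features and word features are concatenated on the
# last axis, projected to the encoder width, passed through a stack of
# relative-position attention layers, and mapped by a fully-connected layer
# to per-label emission scores that feed the CRF.

#' Tagger model configuration
#'
#' Defaults follow the reference recipe: a 1-layer character encoder with
#' \code{cd = 30}, 3 heads and inner width 60; a 2-layer sentence encoder
#' with 8 heads; BIOES labels over the clinical event types. The word
#' embedder is a trainable lookup table of width \code{wd} (a contextual
#' embedder of width 768 drops into the same slot). Because \code{cd + wd}
#' need not be divisible by the head count, the fused features are first
#' mapped by a learned projection to \code{d_model}.
#'
#' @param schema tag schema (fixes the emission dimension \code{d_f})
#' @param char a \code{\link{char_encoder_config}}; \code{NULL} disables the
#'   character path (used for ablation)
#' @param wd word-embedding width
#' @param d_model sentence-encoder width; must be divisible by \code{heads}
#' @param layers number of sentence-encoder layers
#' @param heads sentence-encoder head count
#' @param d_ff sentence-encoder feed-forward inner width
#' @param dropout dropout probability applied to the fused features and each
#'   encoder layer output during training (0 disables; inference never drops)
#' @param rare_unk_p word-dropout probability: during training, a token seen
#'   at most once in the training corpus is replaced by the UNK word id with
#'   this probability, so the UNK embedding is trained and rare/unseen words
#'   are handled through their character features rather than an untrained
#'   row
#' @param norm residual + layer normalization in the sentence encoder
#' @return a \code{ced_config} list
#' @export
ced_config <- function(schema = tag_schema(), char = char_encoder_config(),
                       wd = 100, d_model = 256, layers = 2, heads = 8,
                       d_ff = 2 * d_model, dropout = 0, rare_unk_p = 0.5,
                       norm = TRUE) {
  if (d_model %% heads != 0) stop("`d_model` must be divisible by `heads`")
  if (((d_model %/% heads) %% 2) != 0) stop("per-head width must be even")
  structure(list(schema = schema, char = char, wd = as.integer(wd),
                 d_model = as.integer(d_model), layers = as.integer(layers),
                 heads = as.integer(heads), d_ff = as.integer(d_ff),
                 dropout = dropout, rare_unk_p = rare_unk_p,
                 norm = isTRUE(norm)),
            class = "ced_config")
}

#' Build a tagger model from a training corpus
#'
#' Derives the word and character vocabularies from the corpus tokens and
#' initializes all parameters deterministically from \code{seed}.
#'
#' @param corpus list of \code{\link{labeled_sentence}} objects (training set)
#' @param config a \code{\link{ced_config}}
#' @param seed RNG seed for parameter initialization
#' @return object of class \code{ced_model}
#' @export
ced_model <- function(corpus, config = ced_config(), seed = 1L) {
  tokens <- unlist(lapply(corpus, `[[`, "tokens"))
  wvocab <- word_vocab(tokens)
  cvocab <- char_vocab(tokens)
  freq <- table(tokens)
  use_char <- !is.null(config$char)
  cd_out <- if (use_char) config$char$out_dim else 0L
  d_in <- cd_out + config$wd
  params <- with_local_seed(seed, {
    p <- list()
    if (use_char) {
      p$char <- char_encoder_params(config$char, cvocab,
                                    seed = sample.int(2^31 - 1, 1))
    }
    p$word_emb <- matrix(rnorm(wvocab$size * config$wd, sd = 0.1),
                         wvocab$size, config$wd)
    p$Wp <- matrix(rnorm(d_in * config$d_model, sd = sqrt(2 / (d_in + config$d_model))),
                   d_in, config$d_model)
    p$bp <- numeric(config$d_model)
    p$enc <- lapply(seq_len(config$layers), function(k) {
      tener_params(config$d_model, config$heads, config$d_ff,
                   seed = sample.int(2^31 - 1, 1))
    })
    p$Wo <- matrix(rnorm(config$d_model * config$schema$d_f,
                         sd = sqrt(2 / (config$d_model + config$schema$d_f))),
                   config$d_model, config$schema$d_f)
    p$bo <- numeric(config$schema$d_f)
    p$crf <- crf_params(config$schema$d_f)
    p
  })
  rare <- names(freq)[freq <= 1L]
  structure(list(config = config, params = params, word_vocab = wvocab,
                 char_vocab = cvocab, rare_words = rare),
            class = "ced_model")
}

#' @export
print.ced_model <- function(x, ...) {
  cfg <- x$config
  cat("<ced_model> d_model=", cfg$d_model, ", enc layers=", cfg$layers,
      ", heads=", cfg$heads, ", labels=", cfg$schema$d_f,
      if (is.null(cfg$char)) ", char encoder: off" else
        paste0(", char cd=", cfg$char$cd),
      ", |word vocab|=", x$word_vocab$size, "\n", sep = "")
  invisible(x)
}

# forward through fusion + encoder + output FC, optionally with caches.
# `char_rows`: precomputed l x cd_out char features (training path); when
# NULL they are computed here. `train` enables dropout.
model_forward <- function(tokens, model, char_rows = NULL,
                          return_cache = FALSE, train = FALSE) {
  l <- length(tokens)
  if (l == 0) stop("cannot run the model on an empty sentence")
  cfg <- model$config
  p <- model$params
  use_char <- !is.null(cfg$char)
  if (use_char) {
    if (is.null(char_rows)) {
      char_rows <- embed_sentence_chars(tokens, cfg$char, p$char,
                                        model$char_vocab)
    }
  } else {
    char_rows <- matrix(0, l, 0)
  }
  ids <- word_ids(tokens, model$word_vocab)
  if (train && cfg$rare_unk_p > 0 && length(model$rare_words) > 0) {
    rare <- tokens %in% model$rare_words
    flip <- rare & (stats::runif(l) < cfg$rare_unk_p)
    ids[flip] <- model$word_vocab$unk
  }
  Hw <- p$word_emb[ids, , drop = FALSE]
  H <- cbind(char_rows, Hw)
  drop_p <- if (train) cfg$dropout else 0
  masks <- list()
  if (drop_p > 0) {
    m <- matrix(rbinom(length(H), 1, 1 - drop_p) / (1 - drop_p), nrow(H))
    masks$fuse <- m
    H <- H * m
  }
  X <- add_bias(H %*% p$Wp, p$bp)
  enc_caches <- vector("list", cfg$layers)
  rel <- rel_pos_table(l, cfg$d_model %/% cfg$heads)
  for (k in seq_len(cfg$layers)) {
    fc <- tener_layer(X, p$enc[[k]], norm = cfg$norm, rel = rel,
                      return_cache = TRUE)
    enc_caches[[k]] <- fc$cache
    X <- fc$out
    if (drop_p > 0) {
      m <- matrix(rbinom(length(X), 1, 1 - drop_p) / (1 - drop_p), nrow(X))
      masks[[paste0("enc", k)]] <- m
      X <- X * m
    }
  }
  E <- add_bias(X %*% p$Wo, p$bo)
  if (!return_cache) return(E)
  list(out = E,
       cache = list(tokens = tokens, ids = ids, H = H, X = X,
                    enc_caches = enc_caches, masks = masks,
                    char_rows = char_rows, drop_p = drop_p))
}

# backward through output FC + encoder + fusion. Returns gradients for all
# non-char parameters plus dChar (l x cd_out rows) for the char path.
model_backward <- function(dE, cache, model) {
  cfg <- model$config
  p <- model$params
  g <- list()
  X <- cache$X
  g$Wo <- t(X) %*% dE
  g$bo <- colSums(dE)
  dX <- dE %*% t(p$Wo)
  g$enc <- vector("list", cfg$layers)
  for (k in rev(seq_len(cfg$layers))) {
    m <- cache$masks[[paste0("enc", k)]]
    if (!is.null(m)) dX <- dX * m
    lb <- tener_layer_backward(dX, cache$enc_caches[[k]], p$enc[[k]])
    g$enc[[k]] <- lb$grads
    dX <- lb$dH
  }
  g$Wp <- t(cache$H) %*% dX
  g$bp <- colSums(dX)
  dH <- dX %*% t(p$Wp)
  if (!is.null(cache$masks$fuse)) dH <- dH * cache$masks$fuse
  cd_out <- if (is.null(cfg$char)) 0L else cfg$char$out_dim
  dChar <- if (cd_out > 0) dH[, seq_len(cd_out), drop = FALSE] else NULL
  dHw <- dH[, (cd_out + 1L):ncol(dH), drop = FALSE]
  list(grads = g, dChar = dChar, dHw = dHw, ids = cache$ids)
}

#' Per-token label scores for a sentence
#'
#' Runs the full feature pipeline: character encoding of every token, word
#' embedding lookup, feature fusion, learned projection to the encoder
#' width, the sentence encoder stack, and the emission projection to the
#' label dimension. Deterministic in inference mode.
#'
#' @param tokens character vector of word strings (non-empty)
#' @param model a \code{\link{ced_model}}
#' @return \code{length(tokens)} x \code{d_f} emission score matrix
#' @export
forward_features <- function(tokens, model) {
  model_forward(tokens, model, return_cache = FALSE, train = FALSE)
}

#' Predict BIOES tags for sentences
#'
#' Emission scores from \code{\link{forward_features}} decoded with
#' \code{\link{viterbi_decode}}.
#'
#' @param object a \code{\link{ced_model}}
#' @param corpus list of \code{\link{labeled_sentence}} objects (tags, if
#'   present, are ignored)
#' @param ... unused
#' @return list of \code{\link{labeled_sentence}} objects carrying predicted
#'   tags
#' @export
predict.ced_model <- function(object, corpus, ...) {
  labels <- object$config$schema$labels
  lapply(corpus, function(sent) {
    E <- forward_features(sent$tokens, object)
    y <- viterbi_decode(E, object$params$crf)
    labeled_sentence(sent$tokens, labels[y], validate = "none")
  })
}

tags_to_ids <- function(tags, schema) {
  y <- match(tags, schema$labels)
  if (anyNA(y)) stop("tag sequence contains labels outside the schema")
  y
}
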