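# Character-level word representation: character embedding lookup, one or more
# relative-position attention layers over the character sequence, a resize
# fully-connected layer, and max-pooling over the character axis. Character
# features let the tagger read word shape (affixes, casing residue after digit
# normalization), which matters for clinical terms unseen at training time.

#' Character encoder configuration
#'
#' @param cd character embedding width (must be divisible by \code{heads},
#'   per-head width even)
#' @param heads number of attention heads in the character encoder
#' @param cd_ff feed-forward inner width
#' @param layers number of attention layers over the character sequence
#' @param wl maximum word length in characters; longer words are truncated.
#'   Words are processed at their true (capped) length, so padding characters
#'   never enter attention or pooling and the output is independent of
#'   \code{wl} beyond the word's own length.
#' @param out_dim output width of the resize layer (defaults to \code{cd})
#' @param norm use residual connections + layer normalization in the
#'   character attention layers
#' @return a \code{char_encoder_config} list
#' @export
char_encoder_config <- function(cd = 30, heads = 3, cd_ff = 60, layers = 1,
                                wl = 20, out_dim = cd, norm = TRUE) {
  if (cd %% heads != 0) stop("`cd` must be divisible by `heads`")
  if ((cd %/% heads) %% 2 != 0) stop("per-head width cd/heads must be even")
  if (wl < 1) stop("`wl` must be >= 1")
  structure(list(cd = as.integer(cd), heads = as.integer(heads),
                 cd_ff = as.integer(cd_ff), layers = as.integer(layers),
                 wl = as.integer(wl), out_dim = as.integer(out_dim),
                 norm = isTRUE(norm)),
            class = "char_encoder_config")
}

#' Build a character vocabulary
#'
#' Seeded with printable ASCII and extended with any further characters seen
#' in \code{tokens}. Index 1 is the unknown-character id.
#'
#' @param tokens character vector of words whose characters are added
#' @return a \code{char_vocab} list with the ordered character set and an
#'   index lookup
#' @export
char_vocab <- function(tokens = character(0)) {
  base_chars <- strsplit(rawToChar(as.raw(32:126)), "")[[1]]
  seen <- unique(unlist(strsplit(tokens, "")))
  chars <- unique(c(base_chars, seen))
  index <- seq_along(chars) + 1L # 1 is reserved for UNK
  names(index) <- chars
  structure(list(chars = chars, index = index, unk = 1L,
                 size = length(chars) + 1L),
            class = "char_vocab")
}

char_ids <- function(word, vocab, wl) {
  cs <- strsplit(word, "")[[1]]
  if (length(cs) > wl) cs <- cs[seq_len(wl)]
  ids <- unname(vocab$index[cs])
  ids[is.na(ids)] <- vocab$unk
  ids
}

#' Initialize character-encoder parameters
#'
#' @param config a \code{\link{char_encoder_config}}
#' @param vocab a \code{\link{char_vocab}}
#' @param seed RNG seed
#' @return parameter list: embedding table \code{emb}, attention layers,
#'   resize weights \code{Wr}, \code{br}
#' @export
char_encoder_params <- function(config, vocab, seed = 1L) {
  with_local_seed(seed, {
    emb <- matrix(rnorm(vocab$size * config$cd, sd = 0.1),
                  vocab$size, config$cd)
    layers <- lapply(seq_len(config$layers), function(k) {
      tener_params(config$cd, config$heads, config$cd_ff,
                   seed = sample.int(2^31 - 1, 1))
    })
    Wr <- matrix(rnorm(config$cd * config$out_dim,
                       sd = sqrt(2 / (config$cd + config$out_dim))),
                 config$cd, config$out_dim)
    list(emb = emb, layers = layers, Wr = Wr, br = numeric(config$out_dim))
  })
}

# forward pass for one word; returns the pooled vector and (optionally) the
# cache needed for backprop
char_word_forward <- function(word, config, params, vocab, return_cache = FALSE) {
  if (!nzchar(word)) stop("cannot encode an empty word")
  ids <- char_ids(word, vocab, config$wl)
  E <- params$emb[ids, , drop = FALSE]
  X <- E
  layer_caches <- vector("list", config$layers)
  for (k in seq_len(config$layers)) {
    fc <- tener_layer(X, params$layers[[k]], norm = config$norm,
                      return_cache = TRUE)
    layer_caches[[k]] <- fc$cache
    X <- fc$out
  }
  Z <- add_bias(X %*% params$Wr, params$br)
  amax <- max.col(t(Z), ties.method = "first")
  pooled <- Z[cbind(amax, seq_len(ncol(Z)))]
  if (!return_cache) return(pooled)
  list(out = pooled,
       cache = list(ids = ids, layer_caches = layer_caches, X = X, Z = Z,
                    amax = amax))
}

# backward pass for one word given d(pooled vector); returns a gradient list
# mirroring char_encoder_params (emb gradient as a sparse row list)
char_word_backward <- function(dvec, cache, config, params) {
  Lc <- nrow(cache$Z)
  dZ <- matrix(0, Lc, ncol(cache$Z))
  dZ[cbind(cache$amax, seq_len(ncol(cache$Z)))] <- dvec
  dX <- dZ %*% t(params$Wr)
  dWr <- t(cache$X) %*% dZ
  dbr <- colSums(dZ)
  layer_grads <- vector("list", config$layers)
  for (k in rev(seq_len(config$layers))) {
    lb <- tener_layer_backward(dX, cache$layer_caches[[k]], params$layers[[k]])
    layer_grads[[k]] <- lb$grads
    dX <- lb$dH
  }
  list(dE = dX, ids = cache$ids, layers = layer_grads, dWr = dWr, dbr = dbr)
}

#' Character-level encoding of one word
#'
#' Pipeline: character embedding lookup, \code{layers} relative-position
#' attention layers over the characters, a resize fully-connected layer, then
#' max-pooling over the character axis. Words longer than \code{config$wl}
#' are truncated; shorter words are processed at their true length, so the
#' output never depends on padding.
#'
#' @param word a non-empty word string
#' @param config a \code{\link{char_encoder_config}}
#' @param params parameters from \code{\link{char_encoder_params}}
#' @param vocab a \code{\link{char_vocab}}
#' @return numeric vector of length \code{config$out_dim}
#' @export
encode_word_chars <- function(word, config, params, vocab) {
  char_word_forward(word, config, params, vocab, return_cache = FALSE)
}

#' Character-level encoding of a sentence
#'
#' Stacks \code{\link{encode_word_chars}} row-wise; identical tokens yield
#' identical rows (the character encoder is position-free across words).
#'
#' @param tokens character vector of words (may be empty)
#' @inheritParams encode_word_chars
#' @return numeric matrix, \code{length(tokens)} x \code{config$out_dim}
#' @export
embed_sentence_chars <- function(tokens, config, params, vocab) {
  out <- matrix(0, length(tokens), config$out_dim)
  if (length(tokens) == 0) return(out)
  utoks <- unique(tokens)
  vecs <- vapply(utoks, encode_word_chars, numeric(config$out_dim),
                 config = config, params = params, vocab = vocab)
  t(matrix(vecs, ncol = length(utoks)))[match(tokens, utoks), , drop = FALSE]
}
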