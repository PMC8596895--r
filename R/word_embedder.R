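# Word-level embedding interface. The default implementation is a trainable
# lookup table over the training vocabulary with an UNK row for out-of-
# vocabulary tokens. Any object implementing embed_tokens() with a fixed
# output width `wd` can stand behind the interface; a contextual embedder
# (e.g. a transformer language model's last layer, width 768) plugs in the
# same way but is not bundled.

#' Build a word vocabulary
#'
#' @param tokens character vector of training tokens
#' @return a \code{word_vocab} list; index 1 is the UNK id
#' @export
word_vocab <- function(tokens) {
  words <- unique(tokens)
  index <- seq_along(words) + 1L
  names(index) <- words
  structure(list(words = words, index = index, unk = 1L,
                 size = length(words) + 1L),
            class = "word_vocab")
}

word_ids <- function(tokens, vocab) {
  ids <- unname(vocab$index[tokens])
  ids[is.na(ids)] <- vocab$unk
  ids
}

#' Trainable lookup-table word embedder
#'
#' Returns a word embedder with a \code{size x wd} embedding table initialized
#' deterministically from \code{seed}. Out-of-vocabulary tokens map to the
#' shared UNK row.
#'
#' @param vocab a \code{\link{word_vocab}}
#' @param wd embedding width (>= 1)
#' @param seed RNG seed for the initialization
#' @return object of class \code{word_embedder}
#' @export
lookup_word_embedder <- function(vocab, wd, seed = 1L) {
  if (wd < 1) stop("`wd` must be >= 1")
  emb <- with_local_seed(seed, matrix(rnorm(vocab$size * wd, sd = 0.1),
                                      vocab$size, wd))
  structure(list(kind = "lookup", vocab = vocab, wd = as.integer(wd),
                 emb = emb),
            class = "word_embedder")
}

#' Embed a token sequence
#'
#' @param embedder a \code{word_embedder}
#' @param tokens character vector of tokens
#' @return numeric matrix, \code{length(tokens)} x \code{wd}
#' @export
embed_tokens <- function(embedder, tokens) {
  ids <- word_ids(tokens, embedder$vocab)
  embedder$emb[ids, , drop = FALSE]
}
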