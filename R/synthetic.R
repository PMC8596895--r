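# Desk-scale synthetic corpora with the structure the tagger assumes:
# sentences over a closed filler vocabulary with inserted event spans whose
# surface words carry a type-specific character affix. The affix (not word
# identity) carries the type signal: event word stems are sampled fresh for
# every occurrence, so at test time event words are mostly unseen and the
# character encoder -- not the word lookup -- must generalize. Lexica built
# by generate_lexicon() only ever key and draw from filler words, so
# augmentation can never touch an event token.

# one dedicated marker letter per type; filler words avoid these letters, so
# the trigram affix (marker repeated three times) uniquely identifies a type
type_markers <- c(problem = "q", test = "z", treatment = "x",
                  evidential = "j", occurrence = "k",
                  clinical_department = "w")
filler_alphabet <- setdiff(letters, type_markers)

#' Synthetic corpus configuration
#'
#' @param n_sentences number of sentences to generate
#' @param vocab_size size of the closed filler vocabulary
#' @param max_len maximum sentence length in tokens (minimum is 5)
#' @param proportions named numeric vector over the six event types, summing
#'   to 1: the sampling distribution of span types
#' @param events_mean mean of the (truncated Poisson) events-per-sentence
#'   distribution
#' @param signal word-shape signal strength: the probability that an event
#'   token carries its type-specific character affix
#' @param event_len_range span length range in tokens
#' @param seed RNG seed; generation is fully deterministic given the config
#' @return a \code{synth_config} list
#' @export
synth_config <- function(n_sentences = 500, vocab_size = 50, max_len = 12,
                         proportions = NULL, events_mean = 1.2, signal = 1.0,
                         event_len_range = c(1L, 3L), seed = 1L) {
  types <- names(type_markers)
  if (is.null(proportions)) {
    proportions <- stats::setNames(rep(1 / length(types), length(types)), types)
  }
  if (!setequal(names(proportions), types)) {
    stop("`proportions` must be named by the six event types")
  }
  proportions <- proportions[types]
  if (abs(sum(proportions) - 1) > 1e-8) stop("`proportions` must sum to 1")
  if (n_sentences < 1 || vocab_size < 5 || max_len < 5) {
    stop("counts too small: need n_sentences >= 1, vocab_size >= 5, max_len >= 5")
  }
  if (signal < 0 || signal > 1) stop("`signal` must lie in [0, 1]")
  if (max(event_len_range) > max_len) {
    stop("events longer than the maximum sentence length are infeasible")
  }
  structure(list(n_sentences = as.integer(n_sentences),
                 vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len), proportions = proportions,
                 events_mean = events_mean, signal = signal,
                 event_len_range = as.integer(event_len_range),
                 seed = as.integer(seed)),
            class = "synth_config")
}

random_word <- function(len_range, alphabet = filler_alphabet) {
  n <- sample(len_range[1]:len_range[2], 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

synth_filler_vocab <- function(vocab_size) {
  words <- character(0)
  while (length(words) < vocab_size) {
    words <- unique(c(words, replicate(vocab_size, random_word(c(3L, 6L)))))
  }
  words[seq_len(vocab_size)]
}

#' Generate a synthetic labeled corpus
#'
#' Sentences are built from a closed filler vocabulary; non-overlapping event
#' spans are inserted with types drawn from the configured proportions. Each
#' event token is a freshly sampled stem which, with probability
#' \code{signal}, carries the three-letter affix of its type (a letter that
#' never occurs in filler words), making the task learnable from character
#' shape alone. All tag sequences are schema-valid; generation is
#' deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{synth_config}}
#' @return list of \code{\link{labeled_sentence}} objects with attribute
#'   \code{"filler_vocab"}
#' @export
generate_corpus <- function(config) {
  schema <- tag_schema(names(type_markers))
  with_local_seed(config$seed, {
    vocab <- synth_filler_vocab(config$vocab_size)
    sentences <- vector("list", config$n_sentences)
    for (s in seq_len(config$n_sentences)) {
      L <- sample(5:config$max_len, 1)
      tokens <- sample(vocab, L, replace = TRUE)
      n_ev <- min(stats::rpois(1, config$events_mean),
                  L %/% (max(config$event_len_range) + 1L))
      spans <- list()
      occupied <- rep(FALSE, L)
      for (k in seq_len(n_ev)) {
        le <- sample(config$event_len_range[1]:config$event_len_range[2], 1)
        free_starts <- which(vapply(seq_len(L - le + 1L), function(st) {
          !any(occupied[st:(st + le - 1L)])
        }, logical(1)))
        if (length(free_starts) == 0) next
        st <- free_starts[sample.int(length(free_starts), 1)]
        ty <- sample(names(config$proportions), 1, prob = config$proportions)
        occupied[st:(st + le - 1L)] <- TRUE
        for (tpos in st:(st + le - 1L)) {
          stem <- random_word(c(2L, 4L))
          affix <- if (stats::runif(1) < config$signal) {
            strrep(type_markers[[ty]], 3L)
          } else ""
          tokens[tpos] <- paste0(stem, affix)
        }
        spans[[length(spans) + 1L]] <- event_span(st - 1L, st + le - 1L, ty)
      }
      tags <- encode_spans(L, spans, schema)
      sentences[[s]] <- labeled_sentence(tokens, tags, schema,
                                         validate = "none")
    }
    attr(sentences, "filler_vocab") <- vocab
    sentences
  })
}

#' Generate a synthetic replacement lexicon
#'
#' Keys and candidate words are drawn exclusively from the filler vocabulary
#' (never from event-affixed words), so augmenting a generated corpus can
#' never corrupt a label. Every key receives at least one synonym; antonyms,
#' hypernyms, hyponyms and related words are added with fixed probabilities.
#' Deterministic given \code{seed}.
#'
#' @param vocab character vector of filler words (e.g. the
#'   \code{"filler_vocab"} attribute of \code{\link{generate_corpus}})
#' @param seed RNG seed
#' @param coverage fraction of the vocabulary that receives a lexicon entry
#' @return a \code{\link{lexicon}}
#' @export
generate_lexicon <- function(vocab, seed = 1L, coverage = 0.8) {
  with_local_seed(seed, {
    keys <- sample(vocab, max(1L, round(coverage * length(vocab))))
    entries <- lapply(keys, function(w) {
      others <- setdiff(vocab, w)
      draw <- function(p, maxk) {
        if (stats::runif(1) < p) sample(others, sample.int(maxk, 1)) else character(0)
      }
      list(synonyms = sample(others, 1),
           antonyms = draw(0.3, 2),
           hypernyms = draw(0.4, 2),
           hyponyms = draw(0.4, 2),
           related_words = draw(0.5, 2))
    })
    names(entries) <- keys
    lexicon(entries)
  })
}

#' The packaged worked augmentation example
#'
#' Returns the fixture sentence "She has been worked up with barium enema
#' 09/97 ." with "barium enema" tagged as the test event and every other
#' token outside any span, together with the packaged fixture lexicon
#' (has: synonym "have"; worked: hypernym "set", hyponym "cut", related word
#' "put"; up: antonym "down"). Replacing all replaceable words yields
#' "She have been set down ..."; excluding antonyms leaves "up" in place.
#'
#' @return list with fields \code{sentence} (a
#'   \code{\link{labeled_sentence}}) and \code{lexicon}
#' @export
fixture_paper_example <- function() {
  tokens <- c("She", "has", "been", "worked", "up", "with", "barium",
              "enema", "09/97", ".")
  tags <- c("O", "O", "O", "O", "O", "O", "B-test", "E-test", "O", "O")
  lex_path <- system.file("extdata", "lexicon_worked_example.json",
                          package = "clinevent", mustWork = TRUE)
  list(sentence = labeled_sentence(tokens, tags),
       lexicon = read_lexicon(lex_path))
}
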