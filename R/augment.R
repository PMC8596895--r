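# Label-preserving corpus expansion by priority-ordered lexical replacement
# of non-event words. Replacements are one-for-one token substitutions, so the
# tag sequence of every generated sentence is identical to its source.

relation_order <- c("synonyms", "antonyms", "hypernyms", "hyponyms",
                    "related_words")

#' Construct a replacement lexicon
#'
#' A lexicon maps lowercased words to five ordered candidate-replacement
#' lists: synonyms, antonyms, hypernyms, hyponyms and related words (siblings
#' in a taxonomy). Lookup is case-insensitive; list order fixes which
#' candidate is "first" and therefore makes augmentation deterministic.
#'
#' @param entries named list; each element is a list with any subset of the
#'   five relation fields, each a character vector
#' @return object of class \code{lexicon}
#' @export
lexicon <- function(entries = list()) {
  if (length(entries) > 0 && is.null(names(entries))) {
    stop("`entries` must be a named list keyed by word")
  }
  names(entries) <- tolower(names(entries))
  entries <- lapply(entries, function(e) {
    out <- lapply(relation_order, function(rel) {
      v <- as.character(e[[rel]] %||% character(0))
      v[!duplicated(v)]
    })
    names(out) <- relation_order
    out
  })
  structure(list(entries = entries), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", length(x$entries), " entries\n", sep = "")
  invisible(x)
}

#' Read a replacement lexicon from JSON
#'
#' Expected shape: \code{{"word": {"synonyms": [...], "antonyms": [...],
#' "hypernyms": [...], "hyponyms": [...], "related_words": [...]}, ...}};
#' missing relation fields default to empty.
#'
#' @param path JSON file path
#' @return a \code{\link{lexicon}}
#' @export
read_lexicon <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lexicon(raw)
}

#' Write a lexicon to JSON
#' @param lex a \code{\link{lexicon}}
#' @param path output path
#' @export
write_lexicon <- function(lex, path) {
  jsonlite::write_json(lex$entries, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

lexicon_lookup <- function(lex, word) {
  lex$entries[[tolower(word)]]
}

# a token is eligible for replacement only if it is outside every event span,
# contains no digit, and is not pure punctuation
token_replaceable_shape <- function(token) {
  !grepl("[0-9]", token) && grepl("[[:alpha:]]", token)
}

#' Find replaceable token positions in a sentence
#'
#' Returns the (1-based, ascending) indices of tokens that are tagged
#' \code{"O"}, are not digit-bearing or pure punctuation, and have at least
#' one non-empty candidate list in the lexicon. Only non-event words are ever
#' replaced, which is what keeps augmentation label-preserving.
#'
#' @param sentence a \code{\link{labeled_sentence}}
#' @param lex a \code{\link{lexicon}}
#' @return integer vector of token indices
#' @export
find_replaceable <- function(sentence, lex) {
  idx <- integer(0)
  for (i in seq_along(sentence$tokens)) {
    if (sentence$tags[i] != "O") next
    tok <- sentence$tokens[i]
    if (!token_replaceable_shape(tok)) next
    e <- lexicon_lookup(lex, tok)
    if (is.null(e)) next
    if (any(vapply(e, length, integer(1)) > 0)) idx <- c(idx, i)
  }
  idx
}

#' Select the replacement for a word
#'
#' Scans the candidate lists in priority order synonyms, antonyms, hypernyms,
#' hyponyms, related words (antonyms skipped when \code{exclude_antonyms}) and
#' returns the first element of the first non-empty list, re-capitalized to
#' match the source word. Returns \code{NULL} when no candidate exists.
#'
#' @param word source word
#' @param lex a \code{\link{lexicon}}
#' @param exclude_antonyms skip antonym-sourced replacements
#' @return replacement word or \code{NULL}
#' @export
select_replacement <- function(word, lex, exclude_antonyms = FALSE) {
  e <- lexicon_lookup(lex, word)
  if (is.null(e)) return(NULL)
  rels <- relation_order
  if (exclude_antonyms) rels <- setdiff(rels, "antonyms")
  for (rel in rels) {
    if (length(e[[rel]]) > 0) return(match_case(e[[rel]][1], word))
  }
  NULL
}

#' Generate augmented variants of one sentence
#'
#' Three modes: \code{"all"} replaces every replaceable word (one output
#' sentence at most); \code{"all_no_ant"} does the same but never draws a
#' replacement from an antonym list; \code{"one_no_ant"} emits one new
#' sentence per replaceable position (antonyms excluded), replacing only that
#' position. Outputs identical to the source are suppressed. Every output
#' carries the source tag sequence unchanged.
#'
#' @param sentence a \code{\link{labeled_sentence}}
#' @param lex a \code{\link{lexicon}}
#' @param mode \code{"all"}, \code{"all_no_ant"} or \code{"one_no_ant"}
#' @return list of \code{\link{labeled_sentence}} objects (possibly empty)
#' @export
augment_sentence <- function(sentence, lex,
                             mode = c("all", "all_no_ant", "one_no_ant")) {
  mode <- match.arg(mode)
  idx <- find_replaceable(sentence, lex)
  excl <- mode != "all"
  if (mode %in% c("all", "all_no_ant")) {
    toks <- sentence$tokens
    changed <- FALSE
    for (i in idx) {
      rep_word <- select_replacement(toks[i], lex, exclude_antonyms = excl)
      if (!is.null(rep_word) && rep_word != toks[i]) {
        toks[i] <- rep_word
        changed <- TRUE
      }
    }
    if (!changed) return(list())
    return(list(labeled_sentence(toks, sentence$tags, validate = "none")))
  }
  out <- list()
  for (i in idx) {
    rep_word <- select_replacement(sentence$tokens[i], lex, exclude_antonyms = TRUE)
    if (is.null(rep_word) || rep_word == sentence$tokens[i]) next
    toks <- sentence$tokens
    toks[i] <- rep_word
    out[[length(out) + 1L]] <- labeled_sentence(toks, sentence$tags,
                                                validate = "none")
  }
  out
}

#' Augment a corpus
#'
#' Applies \code{\link{augment_sentence}} to every sentence and appends the
#' generated sentences after the originals. When \code{sample_fraction < 1}
#' the generated pool (originals are always kept) is subsampled uniformly
#' without replacement, deterministically given \code{seed}.
#'
#' @param corpus list of \code{\link{labeled_sentence}} objects
#' @param lex a \code{\link{lexicon}}
#' @param mode augmentation mode, see \code{\link{augment_sentence}}
#' @param sample_fraction fraction of generated sentences to keep, in (0, 1]
#' @param seed RNG seed used for the subsample
#' @return augmented corpus: originals first, then generated sentences
#' @export
augment_corpus <- function(corpus, lex, mode = "all_no_ant",
                           sample_fraction = 1, seed = 1L) {
  if (!is.numeric(sample_fraction) || length(sample_fraction) != 1 ||
      is.na(sample_fraction) || sample_fraction <= 0 || sample_fraction > 1) {
    stop("`sample_fraction` must lie in (0, 1]")
  }
  generated <- list()
  for (sent in corpus) {
    generated <- c(generated, augment_sentence(sent, lex, mode))
  }
  if (sample_fraction < 1 && length(generated) > 0) {
    k <- round(sample_fraction * length(generated))
    keep <- with_local_seed(seed, sample(length(generated), size = k))
    generated <- generated[sort(keep)]
  }
  c(corpus, generated)
}
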