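# Sentence-length adjustment and token normalization applied before tagging.

#' Split an over-long sentence at break punctuation and greedily rejoin
#'
#' Long sentences are first cut immediately after every break-punctuation
#' token (default \code{","} and \code{";"}), then adjacent segments are
#' re-merged left-to-right while the merged length stays within
#' \code{max_len}. A segment that still exceeds \code{max_len} (no internal
#' break punctuation) is hard-split at \code{max_len} so no token is dropped.
#'
#' @param tokens character vector of word strings
#' @param max_len maximum segment length in tokens (>= 1)
#' @param break_puncts character vector of punctuation tokens after which a
#'   cut may occur
#' @return list of token vectors that concatenate to \code{tokens}
#' @export
split_and_rejoin <- function(tokens, max_len, break_puncts = c(",", ";")) {
  max_len <- as.integer(max_len)
  if (is.na(max_len) || max_len < 1L) stop("`max_len` must be >= 1")
  n <- length(tokens)
  if (n == 0) return(list())
  cut_after <- which(tokens %in% break_puncts)
  cut_after <- cut_after[cut_after < n]
  bounds <- c(0L, cut_after, n) # segment i = (bounds[i]+1) : bounds[i+1]
  segs <- mapply(function(a, b) tokens[(a + 1L):b],
                 bounds[-length(bounds)], bounds[-1], SIMPLIFY = FALSE)
  # greedy left-to-right re-merge
  merged <- list()
  for (seg in segs) {
    k <- length(merged)
    if (k > 0 && length(merged[[k]]) + length(seg) <= max_len) {
      merged[[k]] <- c(merged[[k]], seg)
    } else {
      merged[[k + 1L]] <- seg
    }
  }
  # hard split any segment still over max_len
  out <- list()
  for (seg in merged) {
    while (length(seg) > max_len) {
      out[[length(out) + 1L]] <- seg[seq_len(max_len)]
      seg <- seg[-seq_len(max_len)]
    }
    out[[length(out) + 1L]] <- seg
  }
  out
}

#' Split a labeled sentence without cutting through event spans
#'
#' Applies \code{\link{split_and_rejoin}} to a tagged sentence, keeping tags
#' aligned. A cut position that would slice an event span in two is skipped
#' (only positions whose tag does not continue to the next token are eligible),
#' so every output sentence remains schema-valid.
#'
#' @param sentence a \code{\link{labeled_sentence}}
#' @inheritParams split_and_rejoin
#' @return list of \code{\link{labeled_sentence}} objects
#' @export
split_labeled_sentence <- function(sentence, max_len, break_puncts = c(",", ";")) {
  tokens <- sentence$tokens; tags <- sentence$tags
  n <- length(tokens)
  p <- tag_prefixes(tags)
  # positions after which a span continues (cutting there would break it)
  continues <- p %in% c("B", "I")
  # mark ineligible break puncts with a sentinel so split_and_rejoin ignores them
  shadow <- tokens
  bad <- which(tokens %in% break_puncts & continues)
  if (length(bad) > 0) shadow[bad] <- ""
  segs <- split_and_rejoin(shadow, max_len, break_puncts)
  lens <- vapply(segs, length, integer(1))
  ends <- cumsum(lens); starts <- ends - lens + 1L
  mapply(function(a, b) {
    labeled_sentence(tokens[a:b], tags[a:b], validate = "none")
  }, starts, ends, SIMPLIFY = FALSE)
}

#' Normalize tokens: digits to zero, possessive splicing
#'
#' Every decimal digit character is replaced by \code{"0"}; a token that is
#' exactly \code{"'s"} (straight or curly apostrophe) is spliced onto the
#' preceding token and removed. A removed \code{"'s"} must carry tag
#' \code{"O"}, otherwise span alignment would be corrupted and an error is
#' raised. The function is idempotent.
#'
#' @param tokens character vector of word strings
#' @param tags optional aligned tag vector, contracted alongside the tokens
#' @return when \code{tags} is \code{NULL}, the normalized token vector;
#'   otherwise a list with fields \code{tokens} and \code{tags}
#' @examples
#' normalize_tokens(c("patient", "'s", "history"))
#' normalize_tokens(c("09/97")) # "00/00"
#' @export
normalize_tokens <- function(tokens, tags = NULL) {
  if (!is.null(tags) && length(tags) != length(tokens)) {
    stop("tokens and tags differ in length")
  }
  tokens <- gsub("[0-9]", "0", tokens)
  poss <- c("'s", "’s")
  i <- 2L
  while (i <= length(tokens)) {
    if (tokens[i] %in% poss) {
      if (!is.null(tags) && tags[i] != "O") {
        stop(sprintf("possessive token at position %d carries tag '%s'; cannot splice",
                     i, tags[i]))
      }
      tokens[i - 1L] <- paste0(tokens[i - 1L], tokens[i])
      tokens <- tokens[-i]
      if (!is.null(tags)) tags <- tags[-i]
    } else {
      i <- i + 1L
    }
  }
  if (is.null(tags)) tokens else list(tokens = tokens, tags = tags)
}

#' Preprocess a corpus for training or tagging
#'
#' Normalizes every sentence (digit replacement, possessive splicing) and
#' adjusts sentence lengths via \code{\link{split_labeled_sentence}}.
#'
#' @param corpus list of \code{\link{labeled_sentence}} objects
#' @param max_len maximum sentence length after splitting; \code{Inf} disables
#'   splitting
#' @param break_puncts punctuation tokens after which sentences may be cut
#' @return list of \code{\link{labeled_sentence}} objects
#' @export
preprocess_corpus <- function(corpus, max_len = 64, break_puncts = c(",", ";")) {
  out <- list()
  for (sent in corpus) {
    nz <- normalize_tokens(sent$tokens, sent$tags)
    sent <- labeled_sentence(nz$tokens, nz$tags, validate = "none")
    if (is.finite(max_len)) {
      parts <- split_labeled_sentence(sent, max_len, break_puncts)
    } else {
      parts <- list(sent)
    }
    out <- c(out, parts)
  }
  out
}
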