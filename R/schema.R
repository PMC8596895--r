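# Tag schema, labeled sentences, event spans and the BIOES span codec.

#' Default clinical event type vocabulary
#'
#' The six event types used throughout the package: patient problems, tests,
#' treatments, evidentials, occurrences and clinical departments.
#' @export
clinical_event_types <- c("problem", "test", "treatment", "evidential",
                          "occurrence", "clinical_department")

#' Construct a BIOES tag schema
#'
#' Derives the full BIOES label vocabulary from an ordered event-type list.
#' The label order is deterministic given the type order: \code{"O"} first,
#' then \code{B-},\code{I-},\code{E-},\code{S-} blocks per type. The label
#' count \code{d_f} equals \code{4 * length(types) + 1} and is the emission
#' dimension of the tagger.
#'
#' @param types character vector of event-type names (no duplicates)
#' @return object of class \code{tag_schema} with fields \code{types},
#'   \code{labels} and \code{d_f}
#' @examples
#' sch <- tag_schema()
#' sch$d_f # 25 for the six clinical types
#' @export
tag_schema <- function(types = clinical_event_types) {
  if (length(types) < 1 || anyDuplicated(types) > 0) {
    stop("`types` must be a non-empty vector of unique type names")
  }
  labels <- c("O", unlist(lapply(types, function(ty) {
    paste0(c("B", "I", "E", "S"), "-", ty)
  })))
  structure(list(types = types, labels = labels, d_f = length(labels)),
            class = "tag_schema")
}

#' @export
print.tag_schema <- function(x, ...) {
  cat("<tag_schema> ", length(x$types), " event types, ", x$d_f, " labels\n",
      sep = "")
  invisible(x)
}

# split "B-problem" into list(prefix="B", type="problem"); "O" => prefix "O"
parse_tag <- function(tag) {
  if (tag == "O") return(list(prefix = "O", type = NA_character_))
  list(prefix = substr(tag, 1L, 1L), type = substring(tag, 3L))
}

tag_prefixes <- function(tags) {
  ifelse(tags == "O", "O", substr(tags, 1L, 1L))
}

tag_types <- function(tags) {
  ifelse(tags == "O", NA_character_, substring(tags, 3L))
}

#' Typed event span
#'
#' A token interval with an event type. Coordinates are 0-based half-open:
#' \code{start} is the index of the first token, \code{end} one past the last.
#'
#' @param start,end integer token indices, \code{0 <= start < end}
#' @param type event type name
#' @export
event_span <- function(start, end, type) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start) {
    stop(sprintf("invalid span [%s, %s): need 0 <= start < end", start, end))
  }
  structure(list(start = start, end = end, type = as.character(type)),
            class = "event_span")
}

span_key <- function(s) paste(s$start, s$end, s$type, sep = ":")

#' Labeled sentence
#'
#' Tokens plus an aligned BIOES tag sequence.
#'
#' @param tokens character vector of word strings
#' @param tags character vector of BIOES tags, same length as \code{tokens}
#' @param schema tag schema used for validation
#' @param validate one of \code{"labels"} (tags must be in the schema
#'   vocabulary), \code{"strict"} (additionally the sequence must satisfy the
#'   strict BIOES grammar) or \code{"none"}
#' @export
labeled_sentence <- function(tokens, tags, schema = tag_schema(),
                             validate = "labels") {
  tokens <- as.character(tokens); tags <- as.character(tags)
  if (length(tokens) != length(tags)) {
    stop(sprintf("tokens (%d) and tags (%d) differ in length",
                 length(tokens), length(tags)))
  }
  if (validate != "none") {
    bad <- which(!(tags %in% schema$labels))
    if (length(bad) > 0) {
      stop(sprintf("unknown tag '%s' at position %d", tags[bad[1]], bad[1]))
    }
    if (validate == "strict") {
      msg <- check_bioes(tags)
      if (!isTRUE(msg)) stop(msg)
    }
  }
  structure(list(tokens = tokens, tags = tags), class = "labeled_sentence")
}

#' @export
print.labeled_sentence <- function(x, ...) {
  cat(paste(x$tokens, collapse = " "), "\n")
  cat(paste(x$tags, collapse = " "), "\n")
  invisible(x)
}

# TRUE if `tags` follows the strict BIOES grammar, else a message string.
check_bioes <- function(tags) {
  p <- tag_prefixes(tags); ty <- tag_types(tags)
  n <- length(tags)
  for (i in seq_len(n)) {
    if (p[i] %in% c("I", "E")) {
      ok <- i > 1 && p[i - 1] %in% c("B", "I") && identical(ty[i - 1], ty[i])
      if (!ok) return(sprintf("tag '%s' at position %d continues nothing", tags[i], i))
    }
    if (p[i] %in% c("B", "I")) {
      ok <- i < n && p[i + 1] %in% c("I", "E") && identical(ty[i + 1], ty[i])
      if (!ok) return(sprintf("tag '%s' at position %d is not continued", tags[i], i))
    }
  }
  TRUE
}

#' Encode typed spans as a BIOES tag sequence
#'
#' Single-token spans become \code{S-type}; longer spans become
#' \code{B- (I- ...) E-}; all other positions are \code{"O"}. Round-trips with
#' \code{\link{decode_tags}}.
#'
#' @param length sentence length in tokens
#' @param spans list of \code{\link{event_span}} objects (or bare lists with
#'   \code{start}, \code{end}, \code{type}); must be non-overlapping and lie
#'   within \code{[0, length)}
#' @param schema tag schema; span types must belong to it
#' @return character vector of \code{length} BIOES tags
#' @export
encode_spans <- function(length, spans, schema = tag_schema()) {
  length <- as.integer(length)
  tags <- rep("O", length)
  if (base::length(spans) == 0) return(tags)
  starts <- vapply(spans, function(s) as.integer(s$start), integer(1))
  ends <- vapply(spans, function(s) as.integer(s$end), integer(1))
  types <- vapply(spans, function(s) as.character(s$type), character(1))
  for (k in seq_along(spans)) {
    if (starts[k] < 0L || ends[k] > length || starts[k] >= ends[k]) {
      stop(sprintf("span [%d, %d, %s) out of range for length %d",
                   starts[k], ends[k], types[k], length))
    }
    if (!(types[k] %in% schema$types)) {
      stop(sprintf("unknown event type '%s' in span [%d, %d)",
                   types[k], starts[k], ends[k]))
    }
  }
  ord <- order(starts)
  if (any(ends[ord][-base::length(ord)] > starts[ord][-1])) {
    i <- which(ends[ord][-base::length(ord)] > starts[ord][-1])[1]
    stop(sprintf("overlapping spans [%d,%d) and [%d,%d)",
                 starts[ord][i], ends[ord][i],
                 starts[ord][i + 1], ends[ord][i + 1]))
  }
  for (k in seq_along(spans)) {
    s <- starts[k] + 1L; e <- ends[k] # 1-based inclusive range
    if (e - s + 1L == 1L) {
      tags[s] <- paste0("S-", types[k])
    } else {
      tags[s] <- paste0("B-", types[k])
      if (e > s + 1L) tags[(s + 1L):(e - 1L)] <- paste0("I-", types[k])
      tags[e] <- paste0("E-", types[k])
    }
  }
  tags
}

#' Decode a BIOES tag sequence into typed spans
#'
#' In \code{"strict"} mode only well-formed groups (\code{S} or
#' \code{B (I ...) E}) become spans; ill-formed groups are dropped. In
#' \code{"forgiving"} mode every maximal same-type run of non-O tags yields
#' spans as well, splitting at explicit \code{B}/\code{S} starts and after
#' \code{E}/\code{S} ends so that well-formed adjacent spans stay separate;
#' this is what raw (possibly ill-formed) model output is scored with.
#'
#' @param tags character vector of BIOES tags
#' @param mode \code{"strict"} or \code{"forgiving"}
#' @param schema tag schema; unknown labels raise an error
#' @return list of \code{\link{event_span}} objects, 0-based half-open
#' @export
decode_tags <- function(tags, mode = c("strict", "forgiving"),
                        schema = tag_schema()) {
  mode <- match.arg(mode)
  bad <- which(!(tags %in% schema$labels))
  if (length(bad) > 0) {
    stop(sprintf("unknown label '%s' at position %d", tags[bad[1]], bad[1]))
  }
  p <- tag_prefixes(tags); ty <- tag_types(tags)
  n <- length(tags)
  spans <- list()
  i <- 1L
  while (i <= n) {
    if (p[i] == "O") { i <- i + 1L; next }
    t0 <- ty[i]
    if (p[i] == "S") {
      spans[[length(spans) + 1L]] <- list(s = i - 1L, e = i, type = t0, wf = TRUE)
      i <- i + 1L
      next
    }
    start <- i
    wf_start <- p[i] == "B"
    repeat {
      closed <- p[i] == "E"
      can_continue <- !closed && i < n && identical(ty[i + 1], t0) &&
        p[i + 1] %in% c("I", "E") && p[i] %in% c("B", "I")
      i <- i + 1L
      if (!can_continue) break
    }
    end <- i - 1L # last 1-based position of the group
    inner <- if (end - 1L >= start + 1L) p[(start + 1L):(end - 1L)] else character(0)
    wf <- wf_start && p[end] == "E" && all(inner == "I") && end > start
    spans[[length(spans) + 1L]] <- list(s = start - 1L, e = end, type = t0, wf = wf)
  }
  keep <- if (mode == "strict") vapply(spans, `[[`, logical(1), "wf")
          else rep(TRUE, length(spans))
  lapply(spans[keep], function(g) event_span(g$s, g$e, g$type))
}
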