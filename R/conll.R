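# CoNLL-style two-column corpus I/O.

#' Read a CoNLL-style two-column corpus
#'
#' Each non-blank line holds \code{token<TAB>tag} (any whitespace separator is
#' accepted); blank lines separate sentences. Tags are validated against the
#' schema label vocabulary and parse errors report the offending line number.
#'
#' @param path file path (UTF-8)
#' @param schema tag schema used for validation
#' @param validate \code{"labels"} (default), \code{"strict"} (also enforce the
#'   BIOES grammar per sentence) or \code{"none"} (accept any second column;
#'   useful for raw model output)
#' @return list of \code{\link{labeled_sentence}} objects
#' @export
read_conll <- function(path, schema = tag_schema(), validate = "labels") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  toks <- character(0); tgs <- character(0); first_line <- NA_integer_
  flush <- function() {
    if (length(toks) > 0) {
      sent <- tryCatch(
        labeled_sentence(toks, tgs, schema = schema, validate = validate),
        error = function(e) {
          stop(sprintf("%s (sentence starting at line %d of %s)",
                       conditionMessage(e), first_line, path), call. = FALSE)
        })
      sentences[[length(sentences) + 1L]] <<- sent
    }
    toks <<- character(0); tgs <<- character(0); first_line <<- NA_integer_
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*$", line)) { flush(); next }
    parts <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("parse error at line %d of %s: expected 2 columns, got %d",
                   ln, path, length(parts)), call. = FALSE)
    }
    if (length(toks) == 0) first_line <- ln
    toks <- c(toks, parts[1]); tgs <- c(tgs, parts[2])
  }
  flush()
  sentences
}

#' Write a corpus in CoNLL-style two-column format
#'
#' Inverse of \code{\link{read_conll}}: one \code{token<TAB>tag} line per
#' token, a blank line after every sentence. \code{write_conll} then
#' \code{read_conll} is the identity on valid corpora.
#'
#' @param sentences list of \code{\link{labeled_sentence}} objects
#' @param path output file path
#' @export
write_conll <- function(sentences, path) {
  blocks <- vapply(sentences, function(s) {
    paste0(paste(s$tokens, s$tags, sep = "\t", collapse = "\n"), "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(blocks, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
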