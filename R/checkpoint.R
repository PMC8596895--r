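# Model checkpointing as a single JSON document: configuration, vocabularies
# and every parameter array (with dimensions), at full double precision so a
# reloaded model reproduces its predictions exactly.

pack_tree <- function(x) {
  if (is.list(x)) return(lapply(x, pack_tree))
  list(dim = if (is.matrix(x)) dim(x) else length(x), data = as.vector(x))
}

unpack_tree <- function(x) {
  if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
    d <- unlist(x$dim)
    v <- as.numeric(unlist(x$data))
    if (length(d) == 2) return(matrix(v, d[1], d[2]))
    return(v)
  }
  lapply(x, unpack_tree)
}

#' Write a tagger model to a JSON checkpoint
#'
#' @param model a \code{\link{ced_model}}
#' @param path output file path
#' @export
write_model <- function(model, path) {
  cfg <- model$config
  doc <- list(
    format = "clinevent-checkpoint-1",
    config = list(
      types = cfg$schema$types,
      char = if (is.null(cfg$char)) NULL else unclass(cfg$char),
      wd = cfg$wd, d_model = cfg$d_model, layers = cfg$layers,
      heads = cfg$heads, d_ff = cfg$d_ff, dropout = cfg$dropout,
      rare_unk_p = cfg$rare_unk_p, norm = cfg$norm
    ),
    rare_words = model$rare_words,
    word_vocab = model$word_vocab$words,
    char_vocab = model$char_vocab$chars,
    params = pack_tree(model$params)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tagger model from a JSON checkpoint
#'
#' @param path checkpoint path written by \code{\link{write_model}}
#' @return a \code{\link{ced_model}}
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "clinevent-checkpoint-1")) {
    stop("not a clinevent checkpoint: ", path)
  }
  cc <- doc$config$char
  char_cfg <- if (is.null(cc)) NULL else {
    char_encoder_config(cd = cc$cd, heads = cc$heads, cd_ff = cc$cd_ff,
                        layers = cc$layers, wl = cc$wl, out_dim = cc$out_dim,
                        norm = cc$norm)
  }
  cfg <- ced_config(schema = tag_schema(unlist(doc$config$types)),
                    char = char_cfg, wd = doc$config$wd,
                    d_model = doc$config$d_model, layers = doc$config$layers,
                    heads = doc$config$heads, d_ff = doc$config$d_ff,
                    dropout = doc$config$dropout,
                    rare_unk_p = doc$config$rare_unk_p %||% 0.5,
                    norm = doc$config$norm)
  words <- unlist(doc$word_vocab)
  wvocab <- structure(list(words = words,
                           index = stats::setNames(seq_along(words) + 1L, words),
                           unk = 1L, size = length(words) + 1L),
                      class = "word_vocab")
  chars <- unlist(doc$char_vocab)
  cvocab <- structure(list(chars = chars,
                           index = stats::setNames(seq_along(chars) + 1L, chars),
                           unk = 1L, size = length(chars) + 1L),
                      class = "char_vocab")
  structure(list(config = cfg, params = unpack_tree(doc$params),
                 word_vocab = wvocab, char_vocab = cvocab,
                 rare_words = unlist(doc$rare_words) %||% character(0)),
            class = "ced_model")
}
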