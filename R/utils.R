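# Small numeric and structural helpers shared across the package.

#' Numerically stable log-sum-exp
#' @param x numeric vector
#' @return log(sum(exp(x))) computed without overflow
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise / row-wise logsumexp for matrices
col_logsumexp <- function(M) {
  cm <- M[cbind(max.col(t(M), ties.method = "first"), seq_len(ncol(M)))]
  cm[!is.finite(cm)] <- 0 # all -Inf column => log(0); keep -Inf via sum below
  cm + log(colSums(exp(M - rep(cm, each = nrow(M)))))
}

row_logsumexp <- function(M) col_logsumexp(t(M))

# row-wise softmax; tolerates -Inf entries (masked positions get weight 0)
row_softmax <- function(A) {
  mx <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  E <- exp(A - mx)
  E[!is.finite(A)] <- 0
  E / pmax(rowSums(E), .Machine$double.xmin)
}

# add a bias row-vector b to every row of X (fast sweep replacement)
add_bias <- function(X, b) X + rep(b, each = nrow(X))

# multiply every row of X elementwise by the row-vector g
mul_rows <- function(X, g) X * rep(g, each = nrow(X))

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- parameter-tree helpers -------------------------------------------------
# Model parameters are nested lists whose leaves are numeric arrays; these
# walk two trees in lock-step so SGD/momentum updates stay structure-agnostic.

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_map2 <- function(x, y, f) {
  if (is.list(x)) {
    mapply(tree_map2, x, y, MoreArgs = list(f = f), SIMPLIFY = FALSE)
  } else {
    f(x, y)
  }
}

tree_sumsq <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_sumsq, numeric(1))) else sum(x * x)
}

tree_zero <- function(x) tree_map(x, function(a) a * 0)

# mirror the source word's initial capitalization onto a replacement word
match_case <- function(replacement, source) {
  if (grepl("^[[:upper:]]", source)) {
    sub("^(.)", "\\U\\1", replacement, perl = TRUE)
  } else {
    replacement
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
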