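# Relative-position multi-head self-attention ("TENER"-style) layer.
#
# Per head h with per-head width d_k (n heads, n * d_k = d):
#   Q^h = H W_q^h,   K^h = the h-th d_k-wide column slice of H (keys are NOT
#   projected),      V^h = H W_v^h
#   A[t,j] = Q_t K_j' + Q_t R_{t-j}' + u K_j' + v R_{t-j}'
# where R_o is a fixed sinusoidal embedding of the signed offset o. Attention
# is un-scaled (no 1/sqrt(d_k)); the sine components of R are odd in the
# offset, which is what makes the scores direction-aware. Each layer applies
# multi-head attention and a position-wise feed-forward network
# FFN(X) = max(0, X W1 + b1) W2 + b2, with optional residual connections and
# post-layer normalization around both sub-layers.
#
# All forward functions optionally return caches; *_backward functions consume
# them and return input gradients plus parameter gradients (training is plain
# reverse-mode differentiation written out by hand).

#' Sinusoidal relative-position embedding for one offset
#'
#' Interleaved \code{[sin(w_0 o), cos(w_0 o), sin(w_1 o), cos(w_1 o), ...]}
#' with \code{w_i = 10000^(-2 i / d_k)}, \code{i = 0 .. d_k/2 - 1}. At offset
#' 0 this is \code{[0, 1, 0, 1, ...]}; sine components are odd in the offset
#' and cosine components even, encoding direction as well as distance.
#'
#' @param offset signed integer offset \code{t - j}
#' @param d_k even embedding width
#' @return numeric vector of length \code{d_k}
#' @export
rel_pos_embedding <- function(offset, d_k) {
  if (d_k %% 2 != 0) stop("`d_k` must be even")
  i <- 0:(d_k / 2 - 1)
  w <- 10000^(-2 * i / d_k)
  ang <- offset * w
  as.vector(rbind(sin(ang), cos(ang)))
}

#' Table of relative-position embeddings for a sequence length
#'
#' Rows cover offsets \code{-(L-1) .. (L-1)}; offset \code{o} lives in row
#' \code{o + L}.
#'
#' @param L sequence length
#' @param d_k even per-head width
#' @return list with matrix \code{R} ((2L-1) x d_k) and the base length \code{L}
#' @export
rel_pos_table <- function(L, d_k) {
  offsets <- -(L - 1):(L - 1)
  R <- t(vapply(offsets, rel_pos_embedding, numeric(d_k), d_k = d_k))
  if (d_k == 1) R <- matrix(R, ncol = 1) # vapply degenerate shape guard
  list(R = R, L = as.integer(L))
}

#' Initialize one attention + feed-forward layer
#'
#' @param d model width
#' @param heads number of attention heads; must divide \code{d}
#' @param d_ff feed-forward inner width
#' @param seed RNG seed for the initialization
#' @return parameter list (arrays only): per-head \code{W_q}, \code{W_v},
#'   \code{u}, \code{v}; FFN \code{W1,b1,W2,b2}; layer-norm gains/biases
#' @export
tener_params <- function(d, heads, d_ff, seed = 1L) {
  if (d %% heads != 0) stop(sprintf("heads (%d) must divide d (%d)", heads, d))
  dk <- d %/% heads
  if (dk %% 2 != 0) stop(sprintf("per-head width d/heads = %d must be even", dk))
  with_local_seed(seed, {
    rmat <- function(a, b, sd) matrix(rnorm(a * b, sd = sd), a, b)
    list(
      W_q = replicate(heads, rmat(d, dk, sqrt(2 / (d + dk))), simplify = FALSE),
      W_v = replicate(heads, rmat(d, dk, sqrt(2 / (d + dk))), simplify = FALSE),
      u = replicate(heads, rnorm(dk, sd = 0.1), simplify = FALSE),
      v = replicate(heads, rnorm(dk, sd = 0.1), simplify = FALSE),
      W1 = rmat(d, d_ff, sqrt(2 / (d + d_ff))),
      b1 = numeric(d_ff),
      W2 = rmat(d_ff, d, sqrt(2 / (d + d_ff))),
      b2 = numeric(d),
      ln1_g = rep(1, d), ln1_b = numeric(d),
      ln2_g = rep(1, d), ln2_b = numeric(d)
    )
  })
}

# offset index matrix: IDX[t, j] = (t - j) + relL maps into rel table rows
offset_index <- function(L, relL) {
  outer(seq_len(L), seq_len(L), function(t, j) t - j + relL)
}

#' Raw relative-position attention scores for one head
#'
#' Computes the pre-softmax score matrix
#' \code{A[t,j] = Q_t K_j' + Q_t R_(t-j)' + u K_j' + v R_(t-j)'} with
#' \code{Q = H W_q}, \code{K} the head's column slice of \code{H} (keys are
#' unprojected) and no \code{1/sqrt(d_k)} scaling. Masked positions are set to
#' \code{-Inf} so they receive zero weight after softmax.
#'
#' @param H L x d input matrix
#' @param params layer parameters from \code{\link{tener_params}}
#' @param head head index (1-based)
#' @param rel optional precomputed \code{\link{rel_pos_table}} (base length
#'   >= L); built on the fly when \code{NULL}
#' @param mask optional logical vector, \code{FALSE} marks padding positions
#' @return L x L score matrix
#' @export
attention_scores <- function(H, params, head, rel = NULL, mask = NULL) {
  L <- nrow(H)
  dk <- ncol(params$W_q[[head]])
  if (ncol(H) != nrow(params$W_q[[head]])) {
    stop(sprintf("H has width %d but W_q expects %d", ncol(H),
                 nrow(params$W_q[[head]])))
  }
  if (is.null(rel)) rel <- rel_pos_table(L, dk)
  cols <- ((head - 1L) * dk + 1L):(head * dk)
  K <- H[, cols, drop = FALSE]
  Q <- H %*% params$W_q[[head]]
  IDX <- offset_index(L, rel$L)
  P <- Q %*% t(rel$R) # L x (2 relL - 1)
  QR <- matrix(P[cbind(as.vector(row(IDX)), as.vector(IDX))], L, L)
  uK <- as.vector(K %*% params$u[[head]])
  qv <- as.vector(rel$R %*% params$v[[head]])
  A <- Q %*% t(K) + QR + matrix(uK, L, L, byrow = TRUE) + matrix(qv[IDX], L, L)
  if (!is.null(mask)) A[, !mask] <- -Inf
  A
}

attn_head_forward <- function(H, Wq, Wv, u, v, head, rel, mask = NULL) {
  L <- nrow(H)
  dk <- ncol(Wq)
  cols <- ((head - 1L) * dk + 1L):(head * dk)
  K <- H[, cols, drop = FALSE]
  Q <- H %*% Wq
  IDX <- offset_index(L, rel$L)
  P <- Q %*% t(rel$R)
  QR <- matrix(P[cbind(as.vector(row(IDX)), as.vector(IDX))], L, L)
  uK <- as.vector(K %*% u)
  qv <- as.vector(rel$R %*% v)
  A <- Q %*% t(K) + QR + matrix(uK, L, L, byrow = TRUE) + matrix(qv[IDX], L, L)
  if (!is.null(mask)) A[, !mask] <- -Inf
  W <- row_softmax(A)
  V <- H %*% Wv
  list(out = W %*% V, Q = Q, K = K, V = V, W = W, IDX = IDX, cols = cols)
}

attn_head_backward <- function(dOut, cache, H, Wq, Wv, rel, u) {
  L <- nrow(H)
  W <- cache$W; Q <- cache$Q; K <- cache$K; V <- cache$V; IDX <- cache$IDX
  dW <- dOut %*% t(V)
  dV <- t(W) %*% dOut
  rs <- rowSums(dW * W)
  dA <- W * (dW - rs)
  dQ <- dA %*% K
  dK <- t(dA) %*% Q
  cs <- colSums(dA)
  dK <- dK + outer(cs, u)
  du <- as.vector(t(K) %*% cs)
  dP <- matrix(0, L, nrow(rel$R))
  dP[cbind(as.vector(row(IDX)), as.vector(IDX))] <- as.vector(dA)
  dQ <- dQ + dP %*% rel$R
  dv <- as.vector(t(rel$R) %*% colSums(dP))
  dH <- dQ %*% t(Wq) + dV %*% t(Wv)
  dH[, cache$cols] <- dH[, cache$cols] + dK
  list(dH = dH, dWq = t(H) %*% dQ, dWv = t(H) %*% dV, du = du, dv = dv)
}

layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  istd <- 1 / sqrt(v + eps)
  Xhat <- Xc * istd
  out <- add_bias(mul_rows(Xhat, g), b)
  list(out = out, Xhat = Xhat, istd = istd)
}

layernorm_backward <- function(dOut, cache, g) {
  Xhat <- cache$Xhat; istd <- cache$istd
  dXhat <- mul_rows(dOut, g)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * Xhat)
  dX <- istd * (dXhat - m1 - Xhat * m2)
  list(dX = dX, dg = colSums(dOut * Xhat), db = colSums(dOut))
}

ffn_forward <- function(X, W1, b1, W2, b2) {
  Z1 <- add_bias(X %*% W1, b1)
  A1 <- pmax(Z1, 0)
  list(out = add_bias(A1 %*% W2, b2), Z1 = Z1, A1 = A1, X = X)
}

ffn_backward <- function(dOut, cache, W1, W2) {
  dA1 <- dOut %*% t(W2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  list(dX = dZ1 %*% t(W1),
       dW1 = t(cache$X) %*% dZ1, db1 = colSums(dZ1),
       dW2 = t(cache$A1) %*% dOut, db2 = colSums(dOut))
}

#' Apply one relative-position attention + feed-forward layer
#'
#' Multi-head attention (heads concatenated on the last axis) followed by the
#' position-wise FFN. With \code{norm = TRUE} each sub-layer is wrapped in a
#' residual connection and post-layer normalization; with \code{norm = FALSE}
#' both are disabled, which is the configuration the algebraic unit tests use.
#'
#' @param H L x d input matrix
#' @param params layer parameters from \code{\link{tener_params}}
#' @param norm apply residual connections + layer normalization
#' @param mask optional logical keep-vector for padding positions
#' @param rel optional precomputed \code{\link{rel_pos_table}}
#' @param return_cache also return the forward cache (for backprop)
#' @return L x d output matrix, or \code{list(out, cache)} when
#'   \code{return_cache}
#' @export
tener_layer <- function(H, params, norm = TRUE, mask = NULL, rel = NULL,
                        return_cache = FALSE) {
  L <- nrow(H); d <- ncol(H)
  n <- length(params$W_q)
  dk <- d %/% n
  if (n * dk != d || ncol(params$W_q[[1]]) != dk) {
    stop(sprintf("layer expects width %d (heads %d x d_k %d), got %d",
                 length(params$W_q) * ncol(params$W_q[[1]]), n,
                 ncol(params$W_q[[1]]), d))
  }
  if (is.null(rel)) rel <- rel_pos_table(L, dk)
  heads <- vector("list", n)
  att <- matrix(0, L, d)
  for (h in seq_len(n)) {
    hc <- attn_head_forward(H, params$W_q[[h]], params$W_v[[h]],
                            params$u[[h]], params$v[[h]], h, rel, mask)
    heads[[h]] <- hc
    att[, hc$cols] <- hc$out
  }
  if (norm) {
    ln1 <- layernorm_forward(H + att, params$ln1_g, params$ln1_b)
    X1 <- ln1$out
  } else {
    ln1 <- NULL
    X1 <- att
  }
  ffn <- ffn_forward(X1, params$W1, params$b1, params$W2, params$b2)
  if (norm) {
    ln2 <- layernorm_forward(X1 + ffn$out, params$ln2_g, params$ln2_b)
    out <- ln2$out
  } else {
    ln2 <- NULL
    out <- ffn$out
  }
  if (!return_cache) return(out)
  list(out = out,
       cache = list(H = H, heads = heads, X1 = X1, ln1 = ln1, ln2 = ln2,
                    ffn = ffn, rel = rel, norm = norm, n = n, dk = dk))
}

# reverse of tener_layer; returns dH plus a gradient list mirroring `params`
tener_layer_backward <- function(dOut, cache, params) {
  norm <- cache$norm
  n <- cache$n
  g <- list()
  if (norm) {
    ln2b <- layernorm_backward(dOut, cache$ln2, params$ln2_g)
    g$ln2_g <- ln2b$dg; g$ln2_b <- ln2b$db
    dS2 <- ln2b$dX # grad wrt X1 + ffn_out
    dFfnOut <- dS2
    dX1_resid <- dS2
  } else {
    g$ln2_g <- params$ln2_g * 0; g$ln2_b <- params$ln2_b * 0
    dFfnOut <- dOut
    dX1_resid <- 0
  }
  fb <- ffn_backward(dFfnOut, cache$ffn, params$W1, params$W2)
  g$W1 <- fb$dW1; g$b1 <- fb$db1; g$W2 <- fb$dW2; g$b2 <- fb$db2
  dX1 <- fb$dX + dX1_resid
  if (norm) {
    ln1b <- layernorm_backward(dX1, cache$ln1, params$ln1_g)
    g$ln1_g <- ln1b$dg; g$ln1_b <- ln1b$db
    dS1 <- ln1b$dX # grad wrt H + att
    dAtt <- dS1
    dH <- dS1
  } else {
    g$ln1_g <- params$ln1_g * 0; g$ln1_b <- params$ln1_b * 0
    dAtt <- dX1
    dH <- matrix(0, nrow(cache$H), ncol(cache$H))
  }
  g$W_q <- vector("list", n); g$W_v <- vector("list", n)
  g$u <- vector("list", n); g$v <- vector("list", n)
  for (h in seq_len(n)) {
    hc <- cache$heads[[h]]
    hb <- attn_head_backward(dAtt[, hc$cols, drop = FALSE], hc, cache$H,
                             params$W_q[[h]], params$W_v[[h]], cache$rel,
                             params$u[[h]])
    dH <- dH + hb$dH
    g$W_q[[h]] <- hb$dWq; g$W_v[[h]] <- hb$dWv
    g$u[[h]] <- hb$du; g$v[[h]] <- hb$dv
  }
  # reorder gradients to match the canonical parameter layout
  g <- g[c("W_q", "W_v", "u", "v", "W1", "b1", "W2", "b2",
           "ln1_g", "ln1_b", "ln2_g", "ln2_b")]
  list(dH = dH, grads = g)
}
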