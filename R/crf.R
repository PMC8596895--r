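# Linear-chain CRF over per-token label scores: globally normalized sequence
# model with a label-transition table and explicit START/STOP boundary
# scores. Scores arrive already projected to the label dimension d_f (the
# model's final fully-connected layer is the emission projection); the CRF
# adds transition structure, computes the log-partition by the forward
# algorithm and decodes with Viterbi.

#' Initialize CRF parameters
#'
#' Transition table \code{trans[a, b]} scores label \code{b} following label
#' \code{a}; \code{start}/\code{stop} are boundary scores for the first/last
#' label. All zero-initialized, which makes the initial model a per-position
#' softmax.
#'
#' @param d_f number of labels
#' @return list with \code{trans} (d_f x d_f), \code{start}, \code{stop}
#' @export
crf_params <- function(d_f) {
  list(trans = matrix(0, d_f, d_f), start = numeric(d_f), stop = numeric(d_f))
}

check_labels <- function(y, d_f, l) {
  if (length(y) != l) stop(sprintf("label sequence length %d != %d", length(y), l))
  if (any(y < 1L | y > d_f)) stop("label index out of range")
}

#' Score one label sequence under the CRF
#'
#' Sum of per-position emission scores, pairwise transition scores and the
#' START/STOP boundary terms, in the log domain (the unnormalized
#' log-probability of the sequence).
#'
#' @param scores l x d_f emission score matrix
#' @param y integer label sequence (1-based), length l
#' @param crf parameters from \code{\link{crf_params}}
#' @return scalar sequence score
#' @export
crf_sequence_score <- function(scores, y, crf) {
  l <- nrow(scores); y <- as.integer(y)
  check_labels(y, ncol(scores), l)
  s <- crf$start[y[1]] + crf$stop[y[l]] + sum(scores[cbind(seq_len(l), y)])
  if (l > 1) s <- s + sum(crf$trans[cbind(y[-l], y[-1])])
  s
}

#' Log-partition of the CRF by the forward algorithm
#'
#' \code{log sum_y exp(score(y))} over all \code{d_f^l} label sequences,
#' computed in log space in \code{O(l d_f^2)}.
#'
#' @inheritParams crf_sequence_score
#' @return scalar log-partition value
#' @export
crf_log_partition <- function(scores, crf) {
  l <- nrow(scores); d_f <- ncol(scores)
  alpha <- crf$start + scores[1, ]
  if (l > 1) {
    for (i in 2:l) {
      alpha <- col_logsumexp(alpha + crf$trans) + scores[i, ]
    }
  }
  logsumexp(alpha + crf$stop)
}

# forward-backward: logZ plus the marginals needed for the NLL gradient
crf_forward_backward <- function(scores, crf) {
  l <- nrow(scores); d_f <- ncol(scores)
  alpha <- matrix(0, l, d_f)
  alpha[1, ] <- crf$start + scores[1, ]
  if (l > 1) {
    for (i in 2:l) {
      alpha[i, ] <- col_logsumexp(alpha[i - 1, ] + crf$trans) + scores[i, ]
    }
  }
  logZ <- logsumexp(alpha[l, ] + crf$stop)
  beta <- matrix(0, l, d_f)
  beta[l, ] <- crf$stop
  if (l > 1) {
    for (i in (l - 1):1) {
      beta[i, ] <- row_logsumexp(crf$trans +
                                 rep(scores[i + 1, ] + beta[i + 1, ],
                                     each = d_f))
    }
  }
  unary <- exp(alpha + beta - logZ)
  pair <- matrix(0, d_f, d_f)
  if (l > 1) {
    for (i in 2:l) {
      pair <- pair + exp(crf$trans + alpha[i - 1, ] +
                         rep(scores[i, ] + beta[i, ], each = d_f) - logZ)
    }
  }
  list(logZ = logZ, unary = unary, pair = pair)
}

#' Viterbi decoding
#'
#' Returns an argmax-scoring label sequence. Ties are broken toward the
#' lowest label index at every backpointer step, so decoding is
#' deterministic.
#'
#' @inheritParams crf_sequence_score
#' @return integer label sequence of length l
#' @export
viterbi_decode <- function(scores, crf) {
  l <- nrow(scores); d_f <- ncol(scores)
  delta <- crf$start + scores[1, ]
  bp <- matrix(0L, l, d_f)
  if (l > 1) {
    for (i in 2:l) {
      M <- delta + crf$trans # M[a, b] = delta[a] + trans[a, b]
      best_prev <- max.col(t(M), ties.method = "first")
      delta <- M[cbind(best_prev, seq_len(d_f))] + scores[i, ]
      bp[i, ] <- best_prev
    }
  }
  y <- integer(l)
  y[l] <- which.max(delta + crf$stop)
  if (l > 1) {
    for (i in l:2) y[i - 1] <- bp[i, y[i]]
  }
  y
}

#' Negative log-likelihood of gold label sequences
#'
#' \code{sum_i (logZ_i - score(y_i))} over a batch; non-negative, and zero
#' only when the model puts all probability mass on the gold sequences.
#'
#' @param scores_list list of l_i x d_f emission matrices
#' @param y_list list of gold label sequences (1-based integer vectors)
#' @param crf parameters from \code{\link{crf_params}}
#' @return scalar loss
#' @export
crf_nll <- function(scores_list, y_list, crf) {
  stopifnot(length(scores_list) == length(y_list))
  tot <- 0
  for (i in seq_along(scores_list)) {
    tot <- tot + crf_log_partition(scores_list[[i]], crf) -
      crf_sequence_score(scores_list[[i]], y_list[[i]], crf)
  }
  tot
}

# gradient of (logZ - score(y)) wrt emissions and CRF parameters
crf_nll_backward <- function(scores, y, crf) {
  l <- nrow(scores)
  fb <- crf_forward_backward(scores, crf)
  dscores <- fb$unary
  dscores[cbind(seq_len(l), y)] <- dscores[cbind(seq_len(l), y)] - 1
  dtrans <- fb$pair
  if (l > 1) {
    for (i in 2:l) {
      dtrans[y[i - 1], y[i]] <- dtrans[y[i - 1], y[i]] - 1
    }
  }
  dstart <- fb$unary[1, ]; dstart[y[1]] <- dstart[y[1]] - 1
  dstop <- fb$unary[l, ]; dstop[y[l]] <- dstop[y[l]] - 1
  loss <- fb$logZ - crf_sequence_score(scores, y, crf)
  list(loss = loss, dscores = dscores,
       grads = list(trans = dtrans, start = dstart, stop = dstop))
}
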