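# Optimization: SGD with momentum, mini-batches, triangular learning-rate
# schedule (linear warmup to the peak over the first fraction of steps, then
# linear decay to zero), gradient clipping by global norm.

#' Triangular learning-rate schedule
#'
#' Rises linearly from 0 at step 0 to \code{peak} at step
#' \code{w = round(warmup_fraction * total_steps)}, then decays linearly to 0
#' at the final step (\code{total_steps - 1}). Steps are 0-based.
#'
#' @param step 0-based optimizer step, \code{0 <= step < total_steps}
#' @param total_steps total number of optimizer steps
#' @param peak peak learning rate
#' @param warmup_fraction fraction of steps spent warming up, in (0, 1)
#' @return the learning rate at \code{step}
#' @examples
#' triangular_lr(10, 1000) # the peak, 8e-4
#' @export
triangular_lr <- function(step, total_steps, peak = 8e-4,
                          warmup_fraction = 0.01) {
  if (step < 0 || step >= total_steps) {
    stop(sprintf("step %d out of range [0, %d)", step, total_steps))
  }
  w <- round(warmup_fraction * total_steps)
  last <- total_steps - 1
  if (step <= w) {
    if (w == 0) return(if (step == 0) 0 else peak)
    peak * step / w
  } else {
    if (last == w) return(0)
    peak * (last - step) / (last - w)
  }
}

#' Training configuration
#'
#' Defaults are the reference recipe: batches of 16, 100 epochs, SGD with
#' momentum 0.9, peak learning rate 8e-4 reached after the first 1% of steps.
#' Gradient clipping (global norm 5) stabilizes the un-scaled attention.
#'
#' @param batch_size mini-batch size
#' @param epochs number of passes over the training corpus
#' @param lr peak learning rate
#' @param momentum SGD momentum coefficient
#' @param warmup_fraction warmup fraction of the triangular schedule
#' @param clip gradient clipping threshold on the global norm; \code{Inf}
#'   disables
#' @param seed RNG seed for shuffling (and dropout, if enabled)
#' @param shuffle reshuffle the corpus every epoch
#' @return a \code{train_config} list
#' @export
train_config <- function(batch_size = 16, epochs = 100, lr = 8e-4,
                         momentum = 0.9, warmup_fraction = 0.01, clip = 5,
                         seed = 1L, shuffle = TRUE) {
  if (warmup_fraction <= 0 || warmup_fraction >= 1) {
    stop("`warmup_fraction` must lie in (0, 1)")
  }
  if (lr <= 0 || batch_size < 1 || epochs < 1) stop("invalid training config")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 warmup_fraction = warmup_fraction, clip = clip,
                 seed = as.integer(seed), shuffle = isTRUE(shuffle)),
            class = "train_config")
}

# one mini-batch: forward + backward over every sentence, char encodings
# computed once per unique token, gradients averaged over the batch.
train_step <- function(model, batch, y_batch) {
  cfg <- model$config
  p <- model$params
  use_char <- !is.null(cfg$char)
  grads <- tree_zero(p)
  n <- length(batch)
  loss <- 0
  if (use_char) {
    utoks <- unique(unlist(lapply(batch, `[[`, "tokens")))
    ccaches <- vector("list", length(utoks))
    cvecs <- matrix(0, length(utoks), cfg$char$out_dim)
    for (i in seq_along(utoks)) {
      fw <- char_word_forward(utoks[i], cfg$char, p$char, model$char_vocab,
                              return_cache = TRUE)
      ccaches[[i]] <- fw$cache
      cvecs[i, ] <- fw$out
    }
    dcvecs <- matrix(0, length(utoks), cfg$char$out_dim)
  }
  for (b in seq_len(n)) {
    toks <- batch[[b]]$tokens
    char_rows <- if (use_char) {
      cvecs[match(toks, utoks), , drop = FALSE]
    } else NULL
    fw <- model_forward(toks, model, char_rows = char_rows,
                        return_cache = TRUE, train = TRUE)
    cb <- crf_nll_backward(fw$out, y_batch[[b]], p$crf)
    loss <- loss + cb$loss
    grads$crf <- tree_map2(grads$crf, cb$grads, `+`)
    bw <- model_backward(cb$dscores, fw$cache, model)
    for (nm in c("Wp", "bp", "Wo", "bo")) {
      grads[[nm]] <- grads[[nm]] + bw$grads[[nm]]
    }
    grads$enc <- tree_map2(grads$enc, bw$grads$enc, `+`)
    demb <- rowsum(bw$dHw, group = bw$ids)
    rows <- as.integer(rownames(demb))
    grads$word_emb[rows, ] <- grads$word_emb[rows, , drop = FALSE] + demb
    if (use_char) {
      dch <- rowsum(bw$dChar, group = match(toks, utoks))
      rows <- as.integer(rownames(dch))
      dcvecs[rows, ] <- dcvecs[rows, , drop = FALSE] + dch
    }
  }
  if (use_char) {
    for (i in seq_along(utoks)) {
      if (all(dcvecs[i, ] == 0)) next
      cb <- char_word_backward(dcvecs[i, ], ccaches[[i]], cfg$char, p$char)
      grads$char$layers <- tree_map2(grads$char$layers, cb$layers, `+`)
      grads$char$Wr <- grads$char$Wr + cb$dWr
      grads$char$br <- grads$char$br + cb$dbr
      dembr <- rowsum(cb$dE, group = cb$ids)
      rows <- as.integer(rownames(dembr))
      grads$char$emb[rows, ] <- grads$char$emb[rows, , drop = FALSE] + dembr
    }
  }
  grads <- tree_map(grads, function(a) a / n)
  list(loss = loss / n, grads = grads)
}

#' Train the tagger
#'
#' SGD with momentum over mini-batches, triangular learning-rate schedule,
#' gradient clipping, seeded shuffling. When a dev corpus is given, the
#' strict span F1 on it is logged each epoch and the best-dev parameters are
#' returned; otherwise the final parameters are.
#'
#' @param corpus training corpus (list of \code{\link{labeled_sentence}})
#' @param model a \code{\link{ced_model}}
#' @param config a \code{\link{train_config}}
#' @param dev optional development corpus for checkpoint selection
#' @param verbose print one line per epoch
#' @return list with the trained \code{model}, a per-epoch \code{history}
#'   data frame (epoch, mean loss, dev strict F1) and the per-step
#'   \code{lr_trace}
#' @export
train_tagger <- function(corpus, model, config = train_config(), dev = NULL,
                         verbose = FALSE) {
  if (length(corpus) == 0) stop("training corpus is empty")
  schema <- model$config$schema
  y_all <- lapply(corpus, function(s) tags_to_ids(s$tags, schema))
  n <- length(corpus)
  steps_per_epoch <- ceiling(n / config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  vel <- tree_zero(model$params)
  step <- 0L
  lr_trace <- numeric(total_steps)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        dev_f1 = numeric(0))
  best_f1 <- -Inf
  best_params <- NULL
  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- if (config$shuffle) sample.int(n) else seq_len(n)
      epoch_loss <- 0
      for (bs in seq_len(steps_per_epoch)) {
        idx <- ord[((bs - 1L) * config$batch_size + 1L):
                   min(bs * config$batch_size, n)]
        lr <- triangular_lr(step, total_steps, config$lr,
                            config$warmup_fraction)
        lr_trace[step + 1L] <- lr
        st <- train_step(model, corpus[idx], y_all[idx])
        if (!is.finite(st$loss)) {
          stop(sprintf("non-finite loss at epoch %d step %d: %s",
                       epoch, step, format(st$loss)))
        }
        epoch_loss <- epoch_loss + st$loss * length(idx)
        gn <- sqrt(tree_sumsq(st$grads))
        grads <- if (is.finite(config$clip) && gn > config$clip) {
          tree_map(st$grads, function(a) a * (config$clip / gn))
        } else st$grads
        vel <- tree_map2(vel, grads,
                         function(v, g) config$momentum * v + g)
        model$params <- tree_map2(model$params, vel,
                                  function(p, v) p - lr * v)
        step <- step + 1L
      }
      dev_f1 <- NA_real_
      if (!is.null(dev)) {
        pred <- predict(model, dev)
        dev_f1 <- evaluate_corpus(dev, pred, schema = schema)$strict$f1
        if (dev_f1 >= best_f1) {
          best_f1 <- dev_f1
          best_params <- model$params
        }
      }
      history[epoch, ] <- list(epoch, epoch_loss / n, dev_f1)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  dev F1 %s", epoch,
                        epoch_loss / n,
                        if (is.na(dev_f1)) "-" else sprintf("%.4f", dev_f1)))
      }
    }
  })
  if (!is.null(best_params)) model$params <- best_params
  list(model = model, history = history, lr_trace = lr_trace)
}
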