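# Evaluation: strict span P/R/F1 (a prediction counts only when start, end
# and type all match a gold span), lenient span P/R/F1 (one-to-one greedy
# matching by overlap length, type ignored), and type accuracy (fraction of
# leniently matched pairs whose types agree). All corpus-level figures are
# micro-averaged; 0/0 is defined as 0.

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f, tp = tp, fp = fp, fn = fn)
}

#' Strict span precision, recall and F1
#'
#' A predicted span is a true positive iff an identical
#' \code{(start, end, type)} triple exists in the gold annotation of the same
#' sentence. Micro-averaged over the corpus.
#'
#' @param gold,pred lists (one element per sentence, aligned) of span lists;
#'   each span has \code{start}, \code{end}, \code{type}
#' @return list with \code{precision}, \code{recall}, \code{f1} and the
#'   TP/FP/FN counts
#' @export
strict_prf <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop(sprintf("gold has %d sentences but pred has %d",
                 length(gold), length(pred)))
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(gold)) {
    gk <- vapply(gold[[i]], span_key, character(1))
    pk <- vapply(pred[[i]], span_key, character(1))
    m <- sum(pk %in% gk)
    tp <- tp + m
    fp <- fp + length(pk) - m
    fn <- fn + length(gk) - m
  }
  prf(tp, fp, fn)
}

# greedy one-to-one matching of predicted and gold spans by overlap length;
# ties prefer the earlier gold span, then the earlier predicted span
lenient_match <- function(gold_spans, pred_spans) {
  ng <- length(gold_spans); np <- length(pred_spans)
  pairs <- list()
  if (ng == 0 || np == 0) return(pairs)
  ov <- matrix(0, np, ng)
  for (a in seq_len(np)) {
    for (b in seq_len(ng)) {
      ov[a, b] <- max(0, min(pred_spans[[a]]$end, gold_spans[[b]]$end) -
                         max(pred_spans[[a]]$start, gold_spans[[b]]$start))
    }
  }
  used_p <- rep(FALSE, np); used_g <- rep(FALSE, ng)
  repeat {
    ov[used_p, ] <- 0; ov[, used_g] <- 0
    best <- max(ov)
    if (best <= 0) break
    # earliest gold (column), then earliest pred (row), among the maxima
    hit <- which(ov == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE]
    a <- hit[1, 1]; b <- hit[1, 2]
    pairs[[length(pairs) + 1L]] <- list(pred = pred_spans[[a]],
                                        gold = gold_spans[[b]])
    used_p[a] <- TRUE; used_g[b] <- TRUE
  }
  pairs
}

#' Lenient span precision, recall and F1
#'
#' Predicted and gold spans are matched one-to-one per sentence by greatest
#' token overlap (ties to the earlier gold span), ignoring type; matched
#' pairs are span true positives. The matched pairs are returned so type
#' accuracy can be computed on them. One-to-one matching keeps precision
#' bounded by 1 (unrestricted many-to-many matching would not).
#'
#' @inheritParams strict_prf
#' @return list with \code{precision}, \code{recall}, \code{f1}, counts, and
#'   \code{pairs}, the list of matched (pred, gold) span pairs
#' @export
lenient_span_prf <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop(sprintf("gold has %d sentences but pred has %d",
                 length(gold), length(pred)))
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  all_pairs <- list()
  for (i in seq_along(gold)) {
    pairs <- lenient_match(gold[[i]], pred[[i]])
    tp <- tp + length(pairs)
    fp <- fp + length(pred[[i]]) - length(pairs)
    fn <- fn + length(gold[[i]]) - length(pairs)
    all_pairs <- c(all_pairs, pairs)
  }
  out <- prf(tp, fp, fn)
  out$pairs <- all_pairs
  out
}

#' Type accuracy over leniently matched span pairs
#'
#' The fraction of matched (pred, gold) pairs whose event types agree. With
#' no matched pairs the value is reported as 0 and flagged with a warning.
#'
#' @param pairs matched pair list from \code{\link{lenient_span_prf}}
#' @return fraction in [0, 1]; attribute \code{undefined} is \code{TRUE} when
#'   there were no pairs
#' @export
type_accuracy <- function(pairs) {
  if (length(pairs) == 0) {
    warning("no matched span pairs; type accuracy is undefined, reporting 0")
    return(structure(0, undefined = TRUE))
  }
  agree <- vapply(pairs, function(pr) {
    identical(pr$pred$type, pr$gold$type)
  }, logical(1))
  structure(mean(agree), undefined = FALSE)
}

#' Evaluate predicted tags against gold tags
#'
#' Decodes both corpora to spans (gold strictly, predictions with the
#' forgiving decoder by default, since raw model output can be ill-formed
#' BIOES) and computes the three evaluation surfaces: strict span P/R/F1,
#' lenient span P/R/F1 and type accuracy, plus per-type strict F1.
#'
#' @param gold,pred aligned lists of \code{\link{labeled_sentence}} objects
#' @param schema tag schema
#' @param decode_mode decode mode for the predictions (\code{"forgiving"} or
#'   \code{"strict"})
#' @return object of class \code{eval_report}
#' @export
evaluate_corpus <- function(gold, pred, schema = tag_schema(),
                            decode_mode = "forgiving") {
  if (length(gold) != length(pred)) {
    stop(sprintf("gold has %d sentences but pred has %d",
                 length(gold), length(pred)))
  }
  gspans <- lapply(gold, function(s) decode_tags(s$tags, "strict", schema))
  pspans <- lapply(pred, function(s) decode_tags(s$tags, decode_mode, schema))
  strict <- strict_prf(gspans, pspans)
  lenient <- lenient_span_prf(gspans, pspans)
  ta <- withCallingHandlers(type_accuracy(lenient$pairs),
                            warning = function(w) invokeRestart("muffleWarning"))
  per_type <- do.call(rbind, lapply(schema$types, function(ty) {
    gt <- lapply(gspans, function(ss) Filter(function(s) s$type == ty, ss))
    pt <- lapply(pspans, function(ss) Filter(function(s) s$type == ty, ss))
    st <- strict_prf(gt, pt)
    data.frame(type = ty, precision = st$precision, recall = st$recall,
               f1 = st$f1, tp = st$tp, fp = st$fp, fn = st$fn)
  }))
  structure(list(strict = strict,
                 lenient = lenient[c("precision", "recall", "f1",
                                     "tp", "fp", "fn")],
                 type_accuracy = as.numeric(ta),
                 type_accuracy_undefined = isTRUE(attr(ta, "undefined")),
                 per_type = per_type),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("strict   P %.4f  R %.4f  F1 %.4f\n",
              x$strict$precision, x$strict$recall, x$strict$f1))
  cat(sprintf("lenient  P %.4f  R %.4f  F1 %.4f\n",
              x$lenient$precision, x$lenient$recall, x$lenient$f1))
  cat(sprintf("type accuracy %.4f%s\n", x$type_accuracy,
              if (x$type_accuracy_undefined) " (no matched spans)" else ""))
  invisible(x)
}

# serializable form of an eval_report (for the evaluate CLI)
report_to_list <- function(report) {
  list(strict = report$strict[c("precision", "recall", "f1", "tp", "fp", "fn")],
       lenient = report$lenient,
       type_accuracy = report$type_accuracy,
       type_accuracy_undefined = report$type_accuracy_undefined,
       per_type = report$per_type)
}
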