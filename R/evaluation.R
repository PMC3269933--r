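#' Confusion counts from gold and predicted positive sets
#'
#' @param gold character vector: items labeled positive in the gold
#'   standard.
#' @param predicted character vector: items the system called positive.
#' @param universe character vector of all items; `gold` and
#'   `predicted` must be subsets of it.
#' @return object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(gold, predicted, universe) {
  gold <- unique(gold); predicted <- unique(predicted)
  universe <- unique(universe)
  outside <- setdiff(c(gold, predicted), universe)
  if (length(outside))
    stop("items outside universe: ", paste(outside[1:min(3, length(outside))],
                                           collapse = ", "))
  tp <- length(intersect(gold, predicted))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  tn <- length(universe) - tp - fp - fn
  confusion_counts(tp, fp, fn, tn)
}

#' @param tp,fp,fn,tn non-negative integer counts.
#' @rdname confusion
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Precision, recall and F1 from confusion counts
#'
#' All 0/0 cases return 0 (not NaN) so an empty-prediction system
#' scores 0, matching challenge-evaluation practice.
#'
#' @param c a `confusion_counts`.
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  p <- if (c$tp + c$fp > 0) c$tp / (c$tp + c$fp) else 0
  r <- if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy is the ratio of correctly classified instances to all
#' instances, sensitivity the ratio of true positives to all positives,
#' specificity the ratio of true negatives to all negatives.
#'
#' @param c a `confusion_counts` with n > 0.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
accuracy_sens_spec <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$fp + c$fn + c$tn
  if (n <= 0) stop("confusion table is empty")
  acc <- (c$tp + c$tn) / n
  sens <- if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else 0
  spec <- if (c$tn + c$fp > 0) c$tn / (c$tn + c$fp) else 0
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Matthews correlation coefficient
#'
#' MCC = (tp tn - fp fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)), the
#' correlation form of the 2x2 chi-square statistic: mcc^2 * n equals
#' the Pearson chi-square of the confusion table. A zero factor in the
#' denominator gives 0 by convention.
#'
#' @param c a `confusion_counts`.
#' @return numeric in [-1, 1].
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  fn <- as.numeric(c$fn); tn <- as.numeric(c$tn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Area under the interpolated precision/recall curve
#'
#' Walks the ranked list from the top; at each gold item's rank the raw
#' precision is recorded, the interpolated precision at recall r is the
#' maximum raw precision at any recall >= r, and the area is the mean of
#' the interpolated precision over the |gold| recall points. Gold items
#' missing from the ranking contribute 0. Ties must be broken before
#' calling (the ranking is a strict total order).
#'
#' @param ranked character vector of item IDs sorted by confidence
#'   descending.
#' @param gold character vector of positive item IDs, non-empty.
#' @return numeric in [0, 1].
#' @export
auc_ipr <- function(ranked, gold) {
  gold <- unique(gold)
  if (!length(gold)) stop("gold set must be non-empty")
  if (anyDuplicated(ranked)) stop("ranked list contains duplicates")
  is_gold <- ranked %in% gold
  hits <- cumsum(is_gold)
  prec_at_gold <- (hits / seq_along(ranked))[is_gold]  # in rank order
  # pad recall points for gold items not in the ranking with precision 0
  n_missing <- length(gold) - length(prec_at_gold)
  prec_at_gold <- c(prec_at_gold, rep(0, n_missing))
  # interpolate: precision at recall point i = max precision at >= i
  interp <- rev(cummax(rev(prec_at_gold)))
  mean(interp)
}

#' Full metric report from confusion counts
#'
#' @param c a `confusion_counts`.
#' @param auc optional precomputed AUC iP/R to include.
#' @return object of class `metric_report` (named list).
#' @export
metric_report <- function(c, auc = NA_real_) {
  prf <- precision_recall_f1(c)
  ass <- accuracy_sens_spec(c)
  structure(c(as.list(prf), as.list(ass),
              list(mcc = mcc(c), auc_ipr = auc,
                   tp = c$tp, fp = c$fp, fn = c$fn, tn = c$tn)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0(
    "precision   %.4f\nrecall      %.4f\nf1          %.4f\n",
    "accuracy    %.4f\nsensitivity %.4f\nspecificity %.4f\n",
    "mcc         %+.4f\n"),
    x$precision, x$recall, x$f1, x$accuracy, x$sensitivity,
    x$specificity, x$mcc))
  if (!is.na(x$auc_ipr)) cat(sprintf("auc_ipr     %.4f\n", x$auc_ipr))
  cat(sprintf("counts      tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Write a metric report as two-column TSV
#'
#' @param report a `metric_report`.
#' @param path output path.
#' @export
write_metric_report <- function(report, path) {
  keys <- c("precision", "recall", "f1", "accuracy", "sensitivity",
            "specificity", "mcc", "auc_ipr", "tp", "fp", "fn", "tn")
  vals <- vapply(keys, function(k) {
    v <- report[[k]]
    if (is.na(v)) "NA" else sprintf("%.10g", v)
  }, character(1))
  writeLines(c("metric\tvalue", paste(keys, vals, sep = "\t")), path)
  invisible(path)
}

#' Micro-averaged evaluation of document-to-node annotations
#'
#' Confusion counts are pooled over all (document, node) pairs of the
#' universe `docs x nodes` before computing metrics (micro averaging).
#'
#' @param gold named list: doc_id -> character vector of gold node IDs.
#' @param predicted named list: doc_id -> predicted node IDs.
#' @param doc_ids all document IDs evaluated.
#' @param node_ids all allowed node IDs.
#' @param ranked optional data.frame (`doc_id`, `node_id`, `confidence`)
#'   of all scored pairs for AUC iP/R.
#' @return `metric_report`.
#' @export
evaluate_imt <- function(gold, predicted, doc_ids, node_ids,
                         ranked = NULL) {
  pair_key <- function(d, n) {
    if (!length(d) || !length(n)) return(character(0))
    paste(d, n, sep = "\r")
  }
  universe <- as.vector(outer(doc_ids, node_ids, pair_key))
  flat <- function(ann) {
    ids <- intersect(names(ann), doc_ids)
    unlist(lapply(ids, function(d) pair_key(d, intersect(ann[[d]], node_ids))),
           use.names = FALSE)
  }
  cc <- confusion(flat(gold), flat(predicted), universe)
  auc <- NA_real_
  if (!is.null(ranked) && nrow(ranked)) {
    ord <- order(-ranked$confidence, ranked$doc_id, ranked$node_id,
                 method = "radix")
    auc <- auc_ipr(pair_key(ranked$doc_id, ranked$node_id)[ord],
                   flat(gold))
  }
  metric_report(cc, auc)
}
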