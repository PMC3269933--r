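#' Triage-run configuration
#'
#' Collects every knob of a triage (article classification) run: the
#' learner, the feature-selection score, the feature count, the n-gram
#' orders, which corpus composition to train on, and the seed.
#'
#' @param algorithm `"nbm"` (multinomial naive Bayes) or `"svm_poly"`
#'   (polynomial-kernel SVM).
#' @param selection_method `"mi"` or `"chi2"`.
#' @param k number of features to keep.
#' @param orders n-gram orders, `1` or `c(1, 2)`.
#' @param training_split `"train_plus_dev"` or `"dev_only"` -- a
#'   corpus-composition tag interpreted by the caller, recorded in the
#'   model.
#' @param seed integer seed.
#' @param svm_degree,svm_cost polynomial-kernel exponent and cost
#'   (defaults 1 and 1: the unstated upstream-toolkit defaults).
#' @param calibrate logical: map SVM decision values through a logistic
#'   to get graded confidences (default `TRUE`); `FALSE` reproduces raw
#'   hard 0/1 scores.
#' @return object of class `act_config`.
#' @export
act_config <- function(algorithm = c("nbm", "svm_poly"),
                       selection_method = c("chi2", "mi"),
                       k = 400L, orders = c(1L, 2L),
                       training_split = c("train_plus_dev", "dev_only"),
                       seed = 1L, svm_degree = 1, svm_cost = 1,
                       calibrate = TRUE) {
  algorithm <- match.arg(algorithm)
  selection_method <- match.arg(selection_method)
  training_split <- match.arg(training_split)
  orders <- as.integer(orders)
  if (!length(orders) || !all(orders %in% c(1L, 2L)))
    stop("`orders` must be a non-empty subset of c(1, 2)")
  if (k < 1) stop("`k` must be positive")
  structure(list(algorithm = algorithm,
                 selection_method = selection_method,
                 k = as.integer(k), orders = orders,
                 training_split = training_split,
                 seed = as.integer(seed),
                 svm_degree = svm_degree, svm_cost = svm_cost,
                 calibrate = isTRUE(calibrate)),
            class = "act_config")
}

#' The ten named triage run presets
#'
#' Preset labels encode algorithm, n-gram orders (`12` = unigrams and
#' bigrams, `1` = unigrams only), feature count (`1k` = 1000) and
#' training composition (`td` = training+development, `d` = development
#' only). The feature-selection score is not part of the label;
#' chi-square is the default and can be overridden.
#'
#' @param label one of the names returned by `act_preset_names()`.
#' @param ... overrides passed to [act_config()].
#' @return `act_config` (or character vector of labels).
#' @export
act_preset <- function(label, ...) {
  if (!label %in% act_preset_names())
    stop("unknown triage preset '", label, "'; valid presets: ",
         paste(act_preset_names(), collapse = ", "))
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  args <- list(
    algorithm = if (parts[1] == "NBM") "nbm" else "svm_poly",
    orders = if (parts[2] == "12") c(1L, 2L) else 1L,
    k = if (parts[3] == "1k") 1000L else as.integer(parts[3]),
    training_split = if (parts[4] == "td") "train_plus_dev" else "dev_only")
  do.call(act_config, utils::modifyList(args, list(...)))
}

#' @rdname act_preset
#' @export
act_preset_names <- function() {
  c("NBM-12-1k-td", "NBM-12-400-td", "NBM-12-1k-d", "SVM-12-400-d",
    "SVM-12-400-td", "NBM-1-1k-td", "NBM-1-400-td", "NBM-1-1k-d",
    "SVM-1-400-d", "SVM-1-400-td")
}

#' Binary indicator vector of a document over a vocabulary
#'
#' Component i is 1 iff vocabulary term i occurs in the document's
#' n-gram list (title and abstract concatenated, then normalized). All
#' features are uniformly weighted: a term occurring five times still
#' scores 1.
#'
#' @param doc a `document_record`.
#' @param vocabulary ordered character vector of selected terms.
#' @param orders n-gram orders used at training time.
#' @return numeric 0/1 vector of length `length(vocabulary)`.
#' @export
vectorize <- function(doc, vocabulary, orders = c(1L, 2L)) {
  if (!length(vocabulary)) stop("vocabulary must be non-empty")
  ngrams <- extract_ngrams(normalize_and_tokenize(document_text(doc)), orders)
  as.numeric(vocabulary %in% ngrams)
}

act_design_matrix <- function(docs, vocabulary, orders) {
  rows <- lapply(docs, vectorize, vocabulary = vocabulary, orders = orders)
  X <- matrix(unlist(rows), nrow = length(docs), byrow = TRUE)
  dimnames(X) <- list(vapply(docs, `[[`, character(1), "doc_id"), vocabulary)
  X
}

# Multinomial naive Bayes with add-one smoothing over binary indicators.
nbm_train <- function(X, y) {
  classes <- c(0L, 1L)
  V <- ncol(X)
  log_prior <- log(vapply(classes, function(cl) mean(y == cl), numeric(1)))
  log_theta <- do.call(rbind, lapply(classes, function(cl) {
    counts <- colSums(X[y == cl, , drop = FALSE])
    log((counts + 1) / (sum(counts) + V))
  }))
  list(log_prior = log_prior, log_theta = log_theta)
}

nbm_posterior <- function(model, X) {
  scores <- X %*% t(model$log_theta)
  scores <- sweep(scores, 2, model$log_prior, `+`)
  # posterior P(class = 1 | x) by log-sum-exp normalization
  m <- apply(scores, 1, max)
  p <- exp(scores - m)
  p[, 2] / rowSums(p)
}

#' Train a triage classifier
#'
#' Selects the vocabulary on the training corpus only (MI or chi-square
#' top-k), vectorizes the documents as binary indicators and fits the
#' configured learner. Deterministic given the config seed.
#'
#' @param corpus `labeled_corpus` with both classes labeled.
#' @param config an `act_config`.
#' @return object of class `trained_text_classifier`.
#' @export
train_act <- function(corpus, config) {
  stopifnot(inherits(config, "act_config"))
  vocab_scores <- score_vocabulary(corpus, config$orders)
  k <- config$k
  if (k > nrow(vocab_scores)) {
    warning("k = ", k, " exceeds vocabulary size ", nrow(vocab_scores),
            "; clamping")
    k <- nrow(vocab_scores)
  }
  vocabulary <- select_top_k(vocab_scores, k, config$selection_method)
  docs <- corpus_documents(corpus)
  X <- act_design_matrix(docs, vocabulary, config$orders)
  y <- vapply(docs, `[[`, integer(1), "gold_label")
  set.seed(config$seed)
  model <- if (config$algorithm == "nbm") {
    nbm_train(X, y)
  } else {
    svm_train(X, ifelse(y == 1L, 1, -1), cost = config$svm_cost,
              degree = config$svm_degree)
  }
  structure(list(config = config, vocabulary = vocabulary,
                 model = model, recipe_version = "porter-lc-punct-num-v1"),
            class = "trained_text_classifier")
}

#' @export
print.trained_text_classifier <- function(x, ...) {
  cat(sprintf("trained_text_classifier: %s, %d features (%s, orders %s)\n",
              x$config$algorithm, length(x$vocabulary),
              x$config$selection_method,
              paste(x$config$orders, collapse = "+")))
  invisible(x)
}

#' Predict triage labels for a corpus
#'
#' One prediction per document, ranked by confidence descending with
#' ties broken by `doc_id` ascending. NBM confidence is the posterior
#' probability of the positive class; SVM confidence is a logistic
#' mapping of the decision value (or a hard 0/1 score when the model
#' was configured with `calibrate = FALSE`). The predicted label is 1
#' iff confidence >= 0.5.
#'
#' @param model a `trained_text_classifier`.
#' @param corpus `labeled_corpus` (labels may be absent).
#' @return data.frame `doc_id`, `label`, `confidence`, sorted.
#' @export
predict_act <- function(model, corpus) {
  stopifnot(inherits(model, "trained_text_classifier"))
  docs <- corpus_documents(corpus)
  X <- act_design_matrix(docs, model$vocabulary, model$config$orders)
  conf <- if (model$config$algorithm == "nbm") {
    nbm_posterior(model$model, X)
  } else {
    f <- svm_decision(model$model, X)
    if (model$config$calibrate) 1 / (1 + exp(-f)) else as.numeric(f > 0)
  }
  out <- data.frame(doc_id = rownames(X),
                    label = as.integer(conf >= 0.5),
                    confidence = conf, stringsAsFactors = FALSE)
  out <- out[order(-out$confidence, out$doc_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Evaluate triage predictions against gold labels
#'
#' @param predictions data.frame from [predict_act()].
#' @param corpus labeled `labeled_corpus` providing the gold labels.
#' @return `metric_report` including AUC iP/R over the ranking.
#' @export
evaluate_act <- function(predictions, corpus) {
  docs <- corpus_documents(corpus)
  gold_lab <- vapply(docs, `[[`, integer(1), "gold_label")
  if (anyNA(gold_lab)) stop("evaluation corpus contains unlabeled documents")
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  gold_pos <- ids[gold_lab == 1L]
  pred_pos <- predictions$doc_id[predictions$label == 1L]
  cc <- confusion(gold_pos, pred_pos, ids)
  auc <- if (length(gold_pos)) auc_ipr(predictions$doc_id, gold_pos)
         else NA_real_
  metric_report(cc, auc)
}
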