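#' Mapping-run configuration
#'
#' @param algorithm one of `"random_forest"`, `"random_committee"`,
#'   `"nb_tree"`, `"j48"`.
#' @param n_features how many of the 21 pair features to keep after
#'   chi-square selection (21 = no selection).
#' @param negative_sampling `"all"` (every non-gold document-node pair
#'   becomes a negative) or a positive number R (per document, sample
#'   R x number-of-gold-nodes negatives, seeded).
#' @param seed integer seed for samplers and randomized learners.
#' @return object of class `imt_config`.
#' @export
imt_config <- function(algorithm = c("random_forest", "random_committee",
                                     "nb_tree", "j48"),
                       n_features = 21L, negative_sampling = "all",
                       seed = 1L) {
  algorithm <- match.arg(algorithm)
  n_features <- as.integer(n_features)
  if (n_features < 1L || n_features > 21L)
    stop("n_features must be in [1, 21]")
  if (!(identical(negative_sampling, "all") ||
        (is.numeric(negative_sampling) && negative_sampling > 0)))
    stop("negative_sampling must be \"all\" or a positive ratio")
  structure(list(algorithm = algorithm, n_features = n_features,
                 negative_sampling = negative_sampling,
                 seed = as.integer(seed)),
            class = "imt_config")
}

#' The ten named mapping run presets
#'
#' Labels encode learner (`j48`, `rc` = random committee, `rf` = random
#' forest, `nbt` = naive Bayes tree) and the number of features kept.
#'
#' @param label one of the names from `imt_preset_names()`.
#' @param ... overrides passed to [imt_config()].
#' @return `imt_config` (or character vector of labels).
#' @export
imt_preset <- function(label, ...) {
  if (!label %in% imt_preset_names())
    stop("unknown mapping preset '", label, "'; valid presets: ",
         paste(imt_preset_names(), collapse = ", "))
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  algo <- c(j48 = "j48", rc = "random_committee", rf = "random_forest",
            nbt = "nb_tree")[[parts[1]]]
  do.call(imt_config, utils::modifyList(
    list(algorithm = algo, n_features = as.integer(parts[2])), list(...)))
}

#' @rdname imt_preset
#' @export
imt_preset_names <- function() {
  c("j48-21", "rc-21", "rf-21", "j48-14", "rf-12", "rc-12", "rc-14",
    "rf-7", "nbt-7", "rf-15")
}

#' Generate labeled article-node pair instances
#'
#' Positives are the gold (document, node) pairs; negatives are all
#' remaining document x allowed-node pairs, optionally down-sampled per
#' document to `negative_sampling` times that document's positive count
#' (seeded).
#'
#' @param corpus training `labeled_corpus`.
#' @param annotations named list doc_id -> gold node IDs.
#' @param lexicons named list of `node_lexicon` (the allowed nodes).
#' @param stats `scored_vocabulary` term statistics.
#' @param popularity named vector from [compute_node_popularity()].
#' @param config an `imt_config`.
#' @param regex_hook optional named pattern vector from
#'   [read_regex_hook()].
#' @return list with `features` (matrix, 21 columns), `labels` (0/1),
#'   `doc_id`, `node_id`.
#' @export
generate_pair_instances <- function(corpus, annotations, lexicons, stats,
                                    popularity, config,
                                    regex_hook = NULL) {
  if (!length(lexicons)) stop("allowed node set is empty")
  stopifnot(inherits(config, "imt_config"))
  docs <- corpus_documents(corpus)
  node_ids <- vapply(lexicons, `[[`, character(1), "node_id")
  set.seed(config$seed)
  feat <- list(); labs <- integer(0); dids <- character(0); nids <- character(0)
  for (doc in docs) {
    da <- analyze_document(doc)
    gold <- intersect(annotations[[doc$doc_id]], node_ids)
    neg <- setdiff(node_ids, gold)
    if (is.numeric(config$negative_sampling)) {
      n_keep <- min(length(neg),
                    ceiling(config$negative_sampling * length(gold)))
      neg <- sort(sample(neg, n_keep), method = "radix")
    }
    for (nid in c(gold, neg)) {
      lex <- lexicons[[match(nid, node_ids)]]
      feat[[length(feat) + 1L]] <- extract_pair_features(
        da, lex, stats, popularity, regex_hit_for(doc, nid, regex_hook))
      labs <- c(labs, as.integer(nid %in% gold))
      dids <- c(dids, doc$doc_id); nids <- c(nids, nid)
    }
  }
  X <- do.call(rbind, feat)
  list(features = X, labels = labs, doc_id = dids, node_id = nids)
}

# chi-square score of one (possibly continuous) feature against the
# binary label, after a supervised binary split at the threshold that
# maximizes the 2x2 chi-square (candidates: midpoints between
# consecutive distinct sorted values). Returns c(score, threshold).
chi2_discretized <- function(x, y) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(c(score = 0, threshold = NA_real_))
  thresholds <- (ux[-1] + ux[-length(ux)]) / 2
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  best <- c(score = -1, threshold = NA_real_)
  for (t in thresholds) {
    hi <- x > t
    a <- sum(hi & y == 1L); b <- sum(hi & y == 0L)
    s <- chi_square(contingency2x2(a, b, n1 - a, n0 - b))
    if (s > best["score"] + 1e-12) best <- c(score = s, threshold = t)
  }
  best
}

#' Chi-square feature selection over the 21 pair features
#'
#' Continuous features are discretized by the supervised binary split
#' maximizing the 2x2 chi-square against the pair label; features are
#' then ranked by that chi-square, descending, ties broken by feature
#' name ascending.
#'
#' @param instances list from [generate_pair_instances()] (labels
#'   must contain both classes).
#' @param n how many features to return, in [1, 21].
#' @return character vector of feature names, best first; attribute
#'   `scores` carries the full ranking with thresholds.
#' @export
select_pair_features <- function(instances, n) {
  if (n < 1 || n > 21) stop("n must be in [1, 21]")
  y <- instances$labels
  if (length(unique(y)) < 2L) stop("both pair labels must be present")
  X <- instances$features
  sc <- t(apply(X, 2, chi2_discretized, y = y))
  ranking <- data.frame(feature = colnames(X), score = sc[, "score"],
                        threshold = sc[, "threshold"],
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$score, ranking$feature,
                           method = "radix"), ]
  rownames(ranking) <- NULL
  out <- ranking$feature[seq_len(as.integer(n))]
  attr(out, "scores") <- ranking
  out
}

#' Train the article-node pair classifier
#'
#' Applies chi-square feature selection (unless `n_features` is 21),
#' then fits the configured tree learner on the selected columns.
#' Deterministic given the config seed.
#'
#' @param instances list from [generate_pair_instances()].
#' @param config an `imt_config`.
#' @return object of class `trained_pair_classifier`.
#' @export
train_imt <- function(instances, config) {
  stopifnot(inherits(config, "imt_config"))
  y <- instances$labels
  if (length(unique(y)) < 2L)
    stop("training instances must contain both classes")
  features <- if (config$n_features < 21L)
    select_pair_features(instances, config$n_features)
  else imt_feature_names()
  X <- instances$features[, features, drop = FALSE]
  set.seed(config$seed + 1L)
  model <- tree_ensemble_train(X, y, config$algorithm)
  structure(list(config = config, features = as.character(features),
                 selection = attr(features, "scores"),
                 model = model,
                 recipe_version = "porter-lc-punct-num-v1"),
            class = "trained_pair_classifier")
}

#' @export
print.trained_pair_classifier <- function(x, ...) {
  cat(sprintf("trained_pair_classifier: %s over %d features\n",
              x$config$algorithm, length(x$features)))
  invisible(x)
}

#' Score one sentence set and pick the evidence sentence
#'
#' Each sentence scores the sum of the chi-square values of the
#' distinct concept-name unigrams it contains (after normalization);
#' sentences with no concept unigram score 0. The highest-scoring
#' sentence wins; ties go to the longest sentence (raw character
#' count), remaining ties to the earliest offset. An empty sentence
#' list yields an empty sentence with score 0.
#'
#' @param sentences data.frame from [split_sentences()].
#' @param lex a `node_lexicon`.
#' @param stats `scored_vocabulary` term statistics.
#' @param include_synonyms also credit synonym unigrams (default FALSE:
#'   concept-name unigrams only).
#' @param per_occurrence credit every occurrence instead of distinct
#'   unigram types (default FALSE).
#' @return list `sentence` (character), `score` (numeric).
#' @export
extract_evidence_sentence <- function(sentences, lex, stats,
                                      include_synonyms = FALSE,
                                      per_occurrence = FALSE) {
  if (!nrow(sentences)) return(list(sentence = "", score = 0))
  unigrams <- lex$concept_unigrams
  if (include_synonyms) unigrams <- unique(c(unigrams, lex$synonym_unigrams))
  scores <- vapply(sentences$sentence, function(s) {
    toks <- normalize_and_tokenize(s)
    hits <- if (per_occurrence) toks[toks %in% unigrams]
            else intersect(unigrams, toks)
    if (!length(hits)) 0 else sum(term_stat_lookup(stats, hits, "chi2"))
  }, numeric(1), USE.NAMES = FALSE)
  lens <- nchar(sentences$sentence)
  best <- order(-scores, -lens, sentences$start, method = "radix")[1]
  list(sentence = sentences$sentence[best], score = scores[best])
}

#' Predict ontology-node annotations for one document
#'
#' Scores every allowed node against the document; pairs with
#' confidence >= 0.5 are emitted as annotations and carry the evidence
#' sentence selected by [extract_evidence_sentence()]. A document may
#' legitimately yield zero annotations. Output is sorted by confidence
#' descending, ties by node ID.
#'
#' @param model a `trained_pair_classifier`.
#' @param doc a `document_record`.
#' @param lexicons named list of `node_lexicon` (allowed nodes), built
#'   with the same normalization recipe as the model.
#' @param stats `scored_vocabulary` term statistics.
#' @param popularity named vector from [compute_node_popularity()].
#' @param regex_hook optional named pattern vector.
#' @return data.frame `doc_id`, `node_id`, `confidence`, `label`,
#'   `evidence`, `evidence_score` (evidence empty for non-emitted
#'   pairs).
#' @export
predict_imt <- function(model, doc, lexicons, stats, popularity,
                        regex_hook = NULL) {
  stopifnot(inherits(model, "trained_pair_classifier"))
  da <- analyze_document(doc)
  if (!identical(da$recipe_version, model$recipe_version))
    stop("normalization recipe mismatch")
  node_ids <- vapply(lexicons, `[[`, character(1), "node_id")
  feat <- do.call(rbind, lapply(lexicons, function(lex)
    extract_pair_features(da, lex, stats, popularity,
                          regex_hit_for(doc, lex$node_id, regex_hook))))
  X <- feat[, model$features, drop = FALSE]
  conf <- tree_ensemble_prob(model$model, X)
  out <- data.frame(doc_id = doc$doc_id, node_id = node_ids,
                    confidence = conf,
                    label = as.integer(conf >= 0.5),
                    evidence = "", evidence_score = 0,
                    stringsAsFactors = FALSE)
  sentences <- split_sentences(document_text(doc))
  for (i in which(out$label == 1L)) {
    ev <- extract_evidence_sentence(sentences,
                                    lexicons[[match(out$node_id[i], node_ids)]],
                                    stats)
    out$evidence[i] <- ev$sentence
    out$evidence_score[i] <- ev$score
  }
  out <- out[order(-out$confidence, out$node_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Predict annotations for a whole corpus
#'
#' @param corpus `labeled_corpus` of full-text documents.
#' @inheritParams predict_imt
#' @return row-bound data.frame of [predict_imt()] outputs.
#' @export
predict_imt_corpus <- function(model, corpus, lexicons, stats, popularity,
                               regex_hook = NULL) {
  do.call(rbind, lapply(corpus_documents(corpus), function(doc)
    predict_imt(model, doc, lexicons, stats, popularity, regex_hook)))
}
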