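#' 2x2 term/class contingency table
#'
#' @param a term present, class positive
#' @param b term present, class negative
#' @param c term absent, class positive
#' @param d term absent, class negative
#' @return object of class `contingency2x2`.
#' @export
contingency2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers")
  if (sum(counts) <= 0) stop("contingency table must have n > 0")
  structure(as.list(counts), class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  cat(sprintf("2x2 table  a=%d b=%d c=%d d=%d  (n=%d)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Build the presence/class contingency table for one term
#'
#' Presence is document-level binary: a document counts once no matter
#' how often the term occurs in its n-gram list.
#'
#' @param term n-gram string.
#' @param doc_ngrams list of character vectors, one per document (the
#'   document's extracted n-grams).
#' @param labels integer/logical vector of document class labels (1 =
#'   positive), parallel to `doc_ngrams`; no `NA`s allowed.
#' @return `contingency2x2`.
#' @export
build_contingency <- function(term, doc_ngrams, labels) {
  if (!nzchar(term)) stop("`term` must be non-empty")
  if (length(doc_ngrams) != length(labels))
    stop("`doc_ngrams` and `labels` lengths differ")
  if (anyNA(labels)) stop("all documents must be labeled")
  pos <- as.logical(as.integer(labels))
  present <- vapply(doc_ngrams, function(g) term %in% g, logical(1))
  contingency2x2(sum(present & pos), sum(present & !pos),
                 sum(!present & pos), sum(!present & !pos))
}

#' Mutual information of a 2x2 table, in bits
#'
#' MI(F;C) = sum over the four joint cells of p(f,c) log2(p(f,c) /
#' (p(f) p(c))), with the 0 log 0 = 0 convention. Degenerate margins give
#' 0. For binary variables the value lies in [0, 1].
#'
#' @param t a `contingency2x2`.
#' @return non-negative numeric scalar.
#' @export
mutual_information <- function(t) {
  stopifnot(inherits(t, "contingency2x2"))
  joint <- matrix(c(t$a, t$b, t$c, t$d), 2, 2, byrow = TRUE)
  n <- sum(joint)
  p <- joint / n
  pf <- rowSums(p)
  pc <- colSums(p)
  mi <- 0
  for (i in 1:2) for (j in 1:2) {
    if (p[i, j] > 0)
      mi <- mi + p[i, j] * log2(p[i, j] / (pf[i] * pc[j]))
  }
  max(mi, 0)
}

#' Pearson chi-square of a 2x2 table
#'
#' Closed form n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), no continuity
#' correction. Any zero margin returns 0 by convention, so a term present
#' in every document (or none) simply scores 0 and is never selected.
#'
#' @param t a `contingency2x2`.
#' @return non-negative numeric scalar, at most n.
#' @export
chi_square <- function(t) {
  stopifnot(inherits(t, "contingency2x2"))
  # compute in double: margin products overflow 32-bit integers fast
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(0)
  n * (a * d - b * c)^2 / denom
}

#' Score every n-gram of a labeled corpus with MI and chi-square
#'
#' The vocabulary is the union of all n-grams over the corpus; each term
#' is scored by cross-tabulating its document-level presence against the
#' binary class.
#'
#' @param corpus a `labeled_corpus` (see [read_act_corpus()]); every
#'   document must carry a gold label, and both classes must be present.
#' @param orders n-gram orders, subset of `c(1, 2)`.
#' @param label_definition free-text tag recording what the positive
#'   class means; stored in the result for provenance.
#' @return object of class `scored_vocabulary`: data.frame with columns
#'   `term`, `mi`, `chi2`, plus attributes `label_definition` and
#'   `mi_base` (always 2).
#' @export
score_vocabulary <- function(corpus, orders = c(1L, 2L),
                             label_definition = "gold_label") {
  docs <- corpus_documents(corpus)
  labels <- vapply(docs, function(d) {
    if (is.na(d$gold_label)) NA_integer_ else as.integer(d$gold_label)
  }, integer(1))
  if (anyNA(labels)) stop("score_vocabulary: corpus contains unlabeled documents")
  if (length(unique(labels)) < 2L)
    stop("score_vocabulary: both classes must be present")
  doc_ngrams <- lapply(docs, function(d)
    unique(extract_ngrams(normalize_and_tokenize(document_text(d)), orders)))
  scored_vocabulary_from_ngrams(doc_ngrams, labels, label_definition)
}

# Shared core: document n-gram sets + labels -> scored vocabulary.
# Vectorized over terms via a term/doc incidence tabulation.
scored_vocabulary_from_ngrams <- function(doc_ngrams, labels,
                                          label_definition = "gold_label",
                                          vocabulary = NULL) {
  pos <- as.logical(as.integer(labels))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  terms_by_doc <- lapply(doc_ngrams, unique)
  all_terms <- unlist(terms_by_doc, use.names = FALSE)
  doc_is_pos <- rep(pos, lengths(terms_by_doc))
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(all_terms), method = "radix")
  }
  a <- integer(length(vocabulary)); b <- integer(length(vocabulary))
  names(a) <- names(b) <- vocabulary
  tab_pos <- table(factor(all_terms[doc_is_pos], levels = vocabulary))
  tab_neg <- table(factor(all_terms[!doc_is_pos], levels = vocabulary))
  a[] <- as.integer(tab_pos); b[] <- as.integer(tab_neg)
  n <- n_pos + n_neg
  mi <- numeric(length(vocabulary)); chi2 <- numeric(length(vocabulary))
  for (i in seq_along(vocabulary)) {
    t <- contingency2x2(a[i], b[i], n_pos - a[i], n_neg - b[i])
    mi[i] <- mutual_information(t)
    chi2[i] <- chi_square(t)
  }
  out <- data.frame(term = vocabulary, mi = mi, chi2 = chi2,
                    stringsAsFactors = FALSE)
  attr(out, "label_definition") <- label_definition
  attr(out, "mi_base") <- 2L
  class(out) <- c("scored_vocabulary", "data.frame")
  out
}

#' Select the top-k terms of a scored vocabulary
#'
#' Terms are sorted by the chosen score descending with ties broken by
#' term ascending (C-locale), so selection is deterministic and
#' `select_top_k(v, k1)` is always a prefix of `select_top_k(v, k2)` for
#' `k1 <= k2`.
#'
#' @param vocab a `scored_vocabulary`.
#' @param k positive integer; clamped to the vocabulary size.
#' @param method `"mi"` or `"chi2"`.
#' @return character vector of terms, length `min(k, nrow(vocab))`.
#' @export
select_top_k <- function(vocab, k, method = c("mi", "chi2")) {
  method <- match.arg(method)
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("`k` must be a positive integer")
  score <- vocab[[method]]
  ord <- order(-score, vocab$term, method = "radix")
  vocab$term[ord][seq_len(min(as.integer(k), nrow(vocab)))]
}

#' Write / read term statistics as TSV
#'
#' The three-column layout (`term`, `mi`, `chi2`) doubles as the
#' term-statistics input of the ontology-mapping feature extractor and
#' the evidence-sentence scorer.
#'
#' @param vocab a `scored_vocabulary` or any data.frame with columns
#'   `term`, `mi`, `chi2`.
#' @param path file path.
#' @return `read_term_stats` returns a `scored_vocabulary`.
#' @export
write_term_stats <- function(vocab, path) {
  stopifnot(all(c("term", "mi", "chi2") %in% names(vocab)))
  df <- data.frame(term = vocab$term,
                   mi = sprintf("%.12g", vocab$mi),
                   chi2 = sprintf("%.12g", vocab$chi2),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_term_stats
#' @export
read_term_stats <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = c("character", "numeric", "numeric"))
  if (!all(c("term", "mi", "chi2") %in% names(df)))
    stop("term statistics file must have columns term, mi, chi2")
  if (anyDuplicated(df$term)) stop("duplicate terms in term statistics file")
  class(df) <- c("scored_vocabulary", "data.frame")
  df
}

# (0,0) lookup for unknown terms; vectorized.
term_stat_lookup <- function(stats, terms, column) {
  idx <- match(terms, stats$term)
  vals <- stats[[column]][idx]
  vals[is.na(idx)] <- 0
  vals
}
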