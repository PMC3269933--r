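# The 21 article-node pair features, in canonical order. 18 are lexical
# match features over {unigram,bigram} x {concept name, synonyms}; the
# other three are node popularity, an external regex-annotator hit and
# keyword presence.
imt_feature_names <- function() {
  c("perfect_match_concept", "perfect_match_synonym",
    "term_match_uni_concept", "term_match_bi_concept",
    "term_match_uni_synonym", "term_match_bi_synonym",
    "term_match_ratio_uni_concept", "term_match_ratio_bi_concept",
    "term_match_ratio_uni_synonym", "term_match_ratio_bi_synonym",
    "mi_sum_uni_concept", "mi_sum_bi_concept",
    "mi_sum_uni_synonym", "mi_sum_bi_synonym",
    "chi2_sum_uni_concept", "chi2_sum_bi_concept",
    "chi2_sum_uni_synonym", "chi2_sum_bi_synonym",
    "node_popularity", "regex_annotation", "keyword_presence")
}

#' Build the matching lexicon of an ontology node
#'
#' Normalizes the concept name and every synonym into token sequences
#' (kept for contiguous perfect matching) and into deduplicated
#' unigram/bigram sets. By default the concept and synonym n-gram sets
#' are disjoint sources; `synonym_grouping = "combined"` folds the
#' concept name's n-grams into the synonym sets as well.
#'
#' @param node an `ontology_node`.
#' @param synonym_grouping `"disjoint"` (default) or `"combined"`.
#' @return object of class `node_lexicon`.
#' @export
build_node_lexicon <- function(node,
                               synonym_grouping = c("disjoint", "combined")) {
  synonym_grouping <- match.arg(synonym_grouping)
  stopifnot(inherits(node, "ontology_node"))
  name_tokens <- normalize_and_tokenize(node$name)
  syn_tokens <- lapply(node$synonyms, normalize_and_tokenize)
  syn_tokens <- syn_tokens[lengths(syn_tokens) > 0]
  grams <- function(token_seqs, order) {
    unique(unlist(lapply(token_seqs, extract_ngrams, orders = order),
                  use.names = FALSE))
  }
  syn_src <- if (synonym_grouping == "combined")
    c(list(name_tokens), syn_tokens) else syn_tokens
  keyword <- if (is.na(node$keyword)) NA_character_
             else normalize_and_tokenize(node$keyword)
  structure(list(
    node_id = node$node_id,
    name_tokens = name_tokens,
    synonym_tokens = syn_tokens,
    concept_unigrams = grams(list(name_tokens), 1L),
    concept_bigrams = grams(list(name_tokens), 2L),
    synonym_unigrams = grams(syn_src, 1L),
    synonym_bigrams = grams(syn_src, 2L),
    keyword = keyword,
    synonym_grouping = synonym_grouping,
    recipe_version = "porter-lc-punct-num-v1"),
    class = "node_lexicon")
}

#' Term statistics over node-derived n-grams
#'
#' The scoring vocabulary is the union of all unigrams/bigrams derived
#' from the node lexicons. For each term, the binary document class is
#' "this document is annotated with at least one node whose lexicon
#' contains the term"; MI and chi-square then come from the standard
#' 2x2 presence/class table over the training corpus. This per-term
#' class definition is recorded in the result's `label_definition`.
#'
#' @param corpus training `labeled_corpus` (full-text documents).
#' @param annotations named list doc_id -> gold node IDs; must be
#'   non-empty.
#' @param lexicons named list of `node_lexicon`.
#' @return `scored_vocabulary` (term, mi, chi2).
#' @export
compute_term_statistics <- function(corpus, annotations, lexicons) {
  if (!length(annotations) || !sum(lengths(annotations)))
    stop("annotation set is empty")
  docs <- corpus_documents(corpus)
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  doc_ngrams <- lapply(docs, function(d)
    unique(extract_ngrams(normalize_and_tokenize(document_text(d)),
                          c(1L, 2L))))
  term_nodes <- list()    # term -> node ids whose lexicon carries it
  for (lex in lexicons) {
    terms <- unique(c(lex$concept_unigrams, lex$concept_bigrams,
                      lex$synonym_unigrams, lex$synonym_bigrams))
    for (t in terms) term_nodes[[t]] <- c(term_nodes[[t]], lex$node_id)
  }
  vocabulary <- sort(names(term_nodes), method = "radix")
  mi <- numeric(length(vocabulary)); chi2 <- numeric(length(vocabulary))
  ann_nodes <- annotations[intersect(names(annotations), ids)]
  for (i in seq_along(vocabulary)) {
    term <- vocabulary[i]
    carriers <- term_nodes[[term]]
    pos_docs <- names(ann_nodes)[vapply(ann_nodes, function(nn)
      any(nn %in% carriers), logical(1))]
    labels <- as.integer(ids %in% pos_docs)
    present <- vapply(doc_ngrams, function(g) term %in% g, logical(1))
    t2 <- contingency2x2(sum(present & labels == 1L),
                         sum(present & labels == 0L),
                         sum(!present & labels == 1L),
                         sum(!present & labels == 0L))
    mi[i] <- mutual_information(t2)
    chi2[i] <- chi_square(t2)
  }
  out <- data.frame(term = vocabulary, mi = mi, chi2 = chi2,
                    stringsAsFactors = FALSE)
  attr(out, "label_definition") <- "doc annotated with >=1 node carrying term"
  attr(out, "mi_base") <- 2L
  class(out) <- c("scored_vocabulary", "data.frame")
  out
}

#' Node popularity: gold annotation counts per node
#'
#' @param annotations named list doc_id -> node IDs (set semantics:
#'   a node counts once per document).
#' @return named integer vector; looking up an unseen node via
#'   [node_popularity_of()] gives 0.
#' @export
compute_node_popularity <- function(annotations) {
  all_nodes <- unlist(lapply(annotations, unique), use.names = FALSE)
  if (!length(all_nodes)) return(structure(integer(0), names = character(0)))
  tab <- table(all_nodes)
  structure(as.integer(tab), names = names(tab))
}

#' @param popularity named integer vector from [compute_node_popularity()].
#' @param node_id node accession.
#' @rdname compute_node_popularity
#' @export
node_popularity_of <- function(popularity, node_id) {
  v <- unname(popularity[node_id])
  ifelse(is.na(v), 0L, as.integer(v))
}

#' Pre-analyze a document for pair-feature extraction
#'
#' Normalizes once and caches the token sequence plus unigram and
#' bigram sets, so that features against many nodes reuse the work.
#'
#' @param doc a `document_record` with non-empty text.
#' @return object of class `doc_analysis`.
#' @export
analyze_document <- function(doc) {
  tokens <- normalize_and_tokenize(document_text(doc))
  structure(list(doc_id = doc$doc_id, tokens = tokens,
                 unigrams = unique(tokens),
                 bigrams = unique(extract_ngrams(tokens, 2L)),
                 recipe_version = "porter-lc-punct-num-v1"),
            class = "doc_analysis")
}

# contiguous subsequence match of `needle` tokens inside `haystack`
tokens_contain_seq <- function(haystack, needle) {
  n <- length(needle); h <- length(haystack)
  if (n == 0L || h < n) return(FALSE)
  if (n == 1L) return(needle %in% haystack)
  starts <- which(haystack == needle[1])
  starts <- starts[starts + n - 1L <= h]
  for (s in starts) {
    if (all(haystack[s:(s + n - 1L)] == needle)) return(TRUE)
  }
  FALSE
}

#' Extract the 21 features of one article-node pair
#'
#' Matching is performed on normalized (Porter-stemmed) n-grams. Perfect
#' match means the node's full normalized token sequence occurs
#' contiguously in the document's token sequence. Ratios divide matched
#' n-gram types by lexicon n-gram types (0 when the lexicon set is
#' empty); MI/chi-square sums add each distinct matched n-gram's
#' statistic once.
#'
#' @param doc_analysis a `doc_analysis` (or `document_record`, analyzed
#'   on the fly).
#' @param lex a `node_lexicon` built with the same normalization recipe
#'   as `stats`.
#' @param stats `scored_vocabulary` term statistics; unknown terms score
#'   (0, 0).
#' @param popularity named vector from [compute_node_popularity()].
#' @param regex_hit 0/1: external regex-annotator verdict for this pair.
#' @return named numeric vector of the 21 features, in canonical order.
#' @export
extract_pair_features <- function(doc_analysis, lex, stats,
                                  popularity = integer(0), regex_hit = 0L) {
  if (inherits(doc_analysis, "document_record"))
    doc_analysis <- analyze_document(doc_analysis)
  stopifnot(inherits(doc_analysis, "doc_analysis"),
            inherits(lex, "node_lexicon"))
  if (!identical(doc_analysis$recipe_version, lex$recipe_version))
    stop("normalization recipe mismatch between document and lexicon")
  if (!length(doc_analysis$tokens))
    stop("document '", doc_analysis$doc_id, "' has no tokens")

  match_group <- function(lex_terms, doc_terms) {
    if (!length(lex_terms))
      return(list(flag = 0, ratio = 0, mi = 0, chi2 = 0))
    matched <- intersect(lex_terms, doc_terms)
    list(flag = as.numeric(length(matched) > 0),
         ratio = length(matched) / length(lex_terms),
         mi = sum(term_stat_lookup(stats, matched, "mi")),
         chi2 = sum(term_stat_lookup(stats, matched, "chi2")))
  }
  uc <- match_group(lex$concept_unigrams, doc_analysis$unigrams)
  bc <- match_group(lex$concept_bigrams, doc_analysis$bigrams)
  us <- match_group(lex$synonym_unigrams, doc_analysis$unigrams)
  bs <- match_group(lex$synonym_bigrams, doc_analysis$bigrams)

  pm_concept <- as.numeric(tokens_contain_seq(doc_analysis$tokens,
                                              lex$name_tokens))
  pm_synonym <- as.numeric(any(vapply(lex$synonym_tokens, function(s)
    tokens_contain_seq(doc_analysis$tokens, s), logical(1))))
  kw <- if (is.na(lex$keyword)) 0
        else as.numeric(lex$keyword %in% doc_analysis$unigrams)

  out <- c(pm_concept, pm_synonym,
           uc$flag, bc$flag, us$flag, bs$flag,
           uc$ratio, bc$ratio, us$ratio, bs$ratio,
           uc$mi, bc$mi, us$mi, bs$mi,
           uc$chi2, bc$chi2, us$chi2, bs$chi2,
           as.numeric(node_popularity_of(popularity, lex$node_id)),
           as.numeric(regex_hit), kw)
  names(out) <- imt_feature_names()
  out
}

#' Load the pluggable regex-annotator hook
#'
#' TSV of `node_id TAB regular expression` (no header). When supplied,
#' the `regex_annotation` feature of a pair is 1 iff the node's pattern
#' matches the raw document text (case-insensitive, perl syntax);
#' without a hook file the feature is always 0.
#'
#' @param path TSV path.
#' @return named character vector of patterns.
#' @export
read_regex_hook <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L)
      stop("malformed regex hook line ", i, ": ", lines[i])
    out[fields[1]] <- fields[2]
  }
  out
}

regex_hit_for <- function(doc, node_id, regex_hook) {
  if (is.null(regex_hook) || !node_id %in% names(regex_hook)) return(0L)
  as.integer(grepl(regex_hook[[node_id]], document_text(doc),
                   perl = TRUE, ignore.case = TRUE))
}
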