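# Shared helpers for the test suite. All fixtures are built in code.

ref_stats_path <- function() {
  system.file("extdata", "reference_term_stats.tsv", package = "triagemap")
}

synthetic_obo_path <- function() {
  system.file("extdata", "synthetic_methods.obo", package = "triagemap")
}

# tiny labeled corpus built directly from token strings
mini_corpus <- function(texts_pos, texts_neg) {
  docs <- c(
    lapply(seq_along(texts_pos), function(i)
      document_record(sprintf("P%02d", i), body = texts_pos[i],
                      gold_label = 1L)),
    lapply(seq_along(texts_neg), function(i)
      document_record(sprintf("N%02d", i), body = texts_neg[i],
                      gold_label = 0L)))
  labeled_corpus(docs)
}

# independent entropy-based oracle for mutual information (bits)
mi_entropy_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  Hf <- H(c(a + b, c + d) / n)
  Hc <- H(c(a + c, b + d) / n)
  Hfc <- H(c(a, b, c, d) / n)
  Hf + Hc - Hfc
}

# generic Pearson chi-square oracle: sum (O - E)^2 / E over the 4 cells
chi2_pearson_oracle <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  if (any(E == 0)) return(0)
  sum((O - E)^2 / E)
}

random_table <- function() {
  repeat {
    x <- sample.int(60, 4, replace = TRUE) - 1L
    if (sum(x) > 0) return(x)
  }
}

# standard small mapping fixture for pipeline tests
small_imt_fixture <- function(n_docs = 20L, n_nodes = 6L, seed = 5L, ...) {
  make_imt_fixture(imt_fixture_spec(n_nodes = n_nodes, n_docs = n_docs,
                                    seed = seed, ...))
}

imt_assets <- function(fix) {
  lexicons <- lapply(fix$nodes, build_node_lexicon)
  stats <- compute_term_statistics(fix$corpus, fix$annotations, lexicons)
  list(lexicons = lexicons, stats = stats,
       popularity = compute_node_popularity(fix$annotations))
}

imt_micro_f1 <- function(fix, pred) {
  predicted <- split(pred$node_id[pred$label == 1L],
                     pred$doc_id[pred$label == 1L])
  rep <- evaluate_imt(fix$annotations, predicted, corpus_ids(fix$corpus),
                      names(fix$nodes))
  rep$f1
}
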