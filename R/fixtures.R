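# Seeded synthetic corpora with planted signal, so that every pipeline
# stage is testable offline. Pseudo-words are built from
# consonant-vowel syllables and deduplicated on their Porter stems, so
# planted terms survive normalization unambiguously.

tm_make_words <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z", "br", "dr", "gr", "pl", "st", "tr")
  vow <- c("a", "e", "i", "o", "u")
  words <- character(0); stems <- character(0)
  while (length(words) < n) {
    k <- sample(2:3, 1)
    w <- paste0(paste0(sample(cons, k, replace = TRUE),
                       sample(vow, k, replace = TRUE), collapse = ""),
                sample(cons[1:14], 1))
    st <- porter_stem(w)
    if (!st %in% stems && !grepl("[0-9]", w)) {
      words <- c(words, w); stems <- c(stems, st)
    }
  }
  list(words = words, stems = stems)
}

# Zipf-like sampler over a background vocabulary: p(rank r) ~ 1/r.
tm_zipf_sample <- function(words, n) {
  p <- 1 / seq_along(words)
  sample(words, n, replace = TRUE, prob = p / sum(p))
}

#' Specification of a synthetic triage corpus
#'
#' Documents are Zipf-distributed token sequences over a background
#' vocabulary; each of the `n_signal` planted terms occurs in every
#' positive document with probability `signal_rate` (default 1:
#' deterministic planting, so each signal term is perfectly associated
#' with the class and attains chi-square = n and MI = 1 bit at
#' `noise_rate` 0; at least one signal term per positive is guaranteed
#' regardless). Signal terms leak into negatives with probability
#' `noise_rate`. Signal stems are disjoint from background stems by
#' construction.
#'
#' @param n_pos,n_neg document counts (`n_pos` must be positive:
#'   a single-class corpus is unusable downstream).
#' @param n_signal number of planted class-discriminative terms.
#' @param signal_rate per-term planting probability in positives.
#' @param vocab_size background vocabulary size.
#' @param doc_length background tokens per document.
#' @param noise_rate probability a signal term appears in a negative.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return object of class `act_fixture_spec`.
#' @export
act_fixture_spec <- function(n_pos = 100L, n_neg = 100L, n_signal = 5L,
                             signal_rate = 1, vocab_size = 120L,
                             doc_length = 40L, noise_rate = 0, seed = 1L) {
  if (n_pos < 1L) stop("n_pos must be positive (single-class corpus)")
  if (n_neg < 1L) stop("n_neg must be positive (single-class corpus)")
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0,1]")
  if (signal_rate <= 0 || signal_rate > 1) stop("signal_rate must be in (0,1]")
  structure(as.list(environment()), class = "act_fixture_spec")
}

#' Generate a synthetic triage corpus
#'
#' @param spec an [act_fixture_spec()].
#' @return list with `corpus` (a `labeled_corpus`) and `signal`
#'   (character vector of the planted terms' normalized stems).
#' @export
make_act_fixture <- function(spec) {
  stopifnot(inherits(spec, "act_fixture_spec"))
  set.seed(spec$seed)
  lex <- tm_make_words(spec$vocab_size + spec$n_signal)
  signal_words <- lex$words[seq_len(spec$n_signal)]
  signal_stems <- lex$stems[seq_len(spec$n_signal)]
  background <- lex$words[-seq_len(spec$n_signal)]
  gen_doc <- function(id, positive) {
    tokens <- tm_zipf_sample(background, spec$doc_length)
    planted <- if (positive) {
      keep <- stats::runif(spec$n_signal) <= spec$signal_rate
      if (!any(keep)) keep[sample.int(spec$n_signal, 1)] <- TRUE
      signal_words[keep]
    } else {
      signal_words[stats::runif(spec$n_signal) < spec$noise_rate]
    }
    if (length(planted)) {
      at <- sample.int(length(tokens), length(planted))
      tokens[at] <- planted
    }
    document_record(id, body = paste(tokens, collapse = " "),
                    gold_label = as.integer(positive))
  }
  ids_pos <- sprintf("POS%04d", seq_len(spec$n_pos))
  ids_neg <- sprintf("NEG%04d", seq_len(spec$n_neg))
  docs <- c(lapply(ids_pos, gen_doc, positive = TRUE),
            lapply(ids_neg, gen_doc, positive = FALSE))
  list(corpus = labeled_corpus(docs), signal = signal_stems, spec = spec)
}

#' Specification of a synthetic ontology-mapping corpus
#'
#' Emulates an annotated full-text corpus: a generated ontology of
#' `n_nodes` two-token method names (token-disjoint across nodes and
#' from the background vocabulary), documents built from background
#' sentences, and for each gold node a sentence containing the node
#' name verbatim with probability `mention_rate`. A non-gold node's
#' name is mentioned with probability `distractor_rate` per document.
#' The per-document gold count is 1 + Poisson(`annotations_per_doc` -
#' 1), matching the 2.1-2.4 annotations-per-article regime of curated
#' interaction corpora.
#'
#' @param n_nodes,synonyms_per_node ontology size.
#' @param n_docs document count.
#' @param annotations_per_doc target mean gold nodes per document (> 1).
#' @param mention_rate,distractor_rate text-generation probabilities.
#' @param vocab_size,sentences_per_doc,tokens_per_sentence background
#'   text shape.
#' @param seed integer seed.
#' @return object of class `imt_fixture_spec`.
#' @export
imt_fixture_spec <- function(n_nodes = 20L, synonyms_per_node = 1L,
                             n_docs = 100L, annotations_per_doc = 2.2,
                             mention_rate = 1, distractor_rate = 0,
                             vocab_size = 150L, sentences_per_doc = 8L,
                             tokens_per_sentence = 8L, seed = 1L) {
  if (annotations_per_doc <= 0) stop("annotations_per_doc must be > 0")
  if (n_nodes < 2L) stop("need at least 2 nodes")
  structure(as.list(environment()), class = "imt_fixture_spec")
}

#' Generate a synthetic ontology-mapping corpus
#'
#' @param spec an [imt_fixture_spec()].
#' @return list with `corpus` (`labeled_corpus` of full-text documents),
#'   `nodes` (named list of `ontology_node`), `annotations` (named list
#'   doc_id -> gold node IDs).
#' @export
make_imt_fixture <- function(spec) {
  stopifnot(inherits(spec, "imt_fixture_spec"))
  set.seed(spec$seed)
  n_node_tokens <- spec$n_nodes * 2L * (1L + spec$synonyms_per_node)
  lex <- tm_make_words(spec$vocab_size + n_node_tokens)
  node_words <- lex$words[seq_len(n_node_tokens)]
  background <- lex$words[-seq_len(n_node_tokens)]
  node_ids <- sprintf("SYN:%04d", seq_len(spec$n_nodes))
  nodes <- list(); w <- 1L
  for (i in seq_len(spec$n_nodes)) {
    name <- paste(node_words[w:(w + 1L)], collapse = " "); w <- w + 2L
    synonyms <- character(0)
    for (s in seq_len(spec$synonyms_per_node)) {
      synonyms <- c(synonyms, paste(node_words[w:(w + 1L)], collapse = " "))
      w <- w + 2L
    }
    nodes[[node_ids[i]]] <- ontology_node(node_ids[i], name, synonyms)
  }
  bg_sentence <- function() {
    toks <- tm_zipf_sample(background, spec$tokens_per_sentence)
    paste0(toupper(substr(toks[1], 1, 1)), substr(toks[1], 2, nchar(toks[1])),
           " ", paste(toks[-1], collapse = " "), ".")
  }
  mention_sentence <- function(name) {
    toks <- tm_zipf_sample(background, 3L)
    paste0(toupper(substr(toks[1], 1, 1)), substr(toks[1], 2, nchar(toks[1])),
           " ", toks[2], " ", name, " ", toks[3], ".")
  }
  corpus_docs <- list(); annotations <- list()
  for (d in seq_len(spec$n_docs)) {
    doc_id <- sprintf("DOC%04d", d)
    k <- min(spec$n_nodes,
             1L + stats::rpois(1, max(spec$annotations_per_doc - 1, 0)))
    gold <- sort(sample(node_ids, k), method = "radix")
    sentences <- replicate(spec$sentences_per_doc, bg_sentence())
    for (g in gold) {
      if (stats::runif(1) < spec$mention_rate)
        sentences <- c(sentences, mention_sentence(nodes[[g]]$name))
    }
    non_gold <- setdiff(node_ids, gold)
    if (length(non_gold) && stats::runif(1) < spec$distractor_rate) {
      dn <- sample(non_gold, 1)
      sentences <- c(sentences, mention_sentence(nodes[[dn]]$name))
    }
    sentences <- sample(sentences)          # shuffle sentence order
    corpus_docs[[d]] <- document_record(doc_id,
                                        body = paste(sentences, collapse = " "))
    annotations[[doc_id]] <- gold
  }
  list(corpus = labeled_corpus(corpus_docs), nodes = nodes,
       annotations = annotations, spec = spec)
}

#' Write a complete fixture directory tree in external formats
#'
#' Emits the triage corpus as TSV and/or the mapping fixture as a
#' plain-text document directory, an OBO ontology and an annotation
#' TSV, so integration tests exercise the real readers.
#'
#' @param fixture result of [make_act_fixture()] or
#'   [make_imt_fixture()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(fixture$signal)) {
    write_act_corpus(fixture$corpus, file.path(dir, "corpus.tsv"))
    writeLines(fixture$signal, file.path(dir, "signal_terms.txt"))
  } else {
    docdir <- file.path(dir, "docs")
    dir.create(docdir, showWarnings = FALSE)
    for (doc in corpus_documents(fixture$corpus)) {
      writeLines(doc$body, file.path(docdir, paste0(doc$doc_id, ".txt")))
    }
    write_obo(fixture$nodes, file.path(dir, "ontology.obo"))
    write_annotations(fixture$annotations, file.path(dir, "annotations.tsv"))
  }
  invisible(dir)
}
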