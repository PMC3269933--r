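test_that("node lexicon normalizes names, synonyms and keyword", {
  node <- ontology_node("MI:0018", "two hybrid")
  lex <- build_node_lexicon(node)
  expect_setequal(lex$concept_unigrams, c("two", "hybrid"))
  expect_equal(lex$concept_bigrams, "two hybrid")
  expect_length(lex$synonym_unigrams, 0L)

  node2 <- ontology_node("MI:0006", "anti bait coimmunoprecipitation",
                         synonyms = "anti bait immunoprecipitation",
                         keyword = "coimmunoprecipitation")
  lex2 <- build_node_lexicon(node2)
  expect_true("immunoprecipit" %in% lex2$synonym_unigrams)  # stemmed
  expect_equal(lex2$keyword, "coimmunoprecipit")
  # single-token concept has no bigrams
  lex3 <- build_node_lexicon(ontology_node("MI:0999", "crosslinking"))
  expect_length(lex3$concept_bigrams, 0L)
  # combined grouping folds concept n-grams into the synonym sets
  lex4 <- build_node_lexicon(node2, synonym_grouping = "combined")
  expect_true(all(lex2$concept_unigrams %in% lex4$synonym_unigrams))
})

test_that("pair features match reference statistics on worked examples", {
  stats <- read_term_stats(ref_stats_path())
  lex <- build_node_lexicon(ontology_node("MI:0018", "two hybrid"))
  doc <- document_record("D1",
    body = "We performed a yeast two-hybrid screen on these proteins")
  f <- extract_pair_features(doc, lex, stats)
  expect_length(f, 21L)
  expect_named(f, triagemap:::imt_feature_names())
  expect_equal(f[["perfect_match_concept"]], 1)
  expect_equal(f[["term_match_ratio_uni_concept"]], 1.0)
  expect_equal(f[["chi2_sum_bi_concept"]], 1225.574)
  expect_equal(f[["mi_sum_bi_concept"]], 0.439)

  doc2 <- document_record("D2", body = "only hybrid appears here")
  f2 <- extract_pair_features(doc2, lex, stats)
  expect_equal(f2[["perfect_match_concept"]], 0)
  expect_equal(f2[["term_match_ratio_uni_concept"]], 0.5)
  expect_equal(f2[["mi_sum_uni_concept"]], 0.398)
  expect_equal(f2[["chi2_sum_uni_concept"]], 1041.587496)

  doc3 <- document_record("D3", body = "completely unrelated prose text")
  f3 <- extract_pair_features(doc3, lex, stats)
  match_feats <- setdiff(triagemap:::imt_feature_names(),
                         c("node_popularity", "regex_annotation",
                           "keyword_presence"))
  expect_true(all(f3[match_feats] == 0))
})

test_that("term_match flags equal (ratio > 0) and sums are monotone", {
  stats <- read_term_stats(ref_stats_path())
  set.seed(13)
  fix <- small_imt_fixture(n_docs = 8L, n_nodes = 4L, seed = 13L)
  lexicons <- lapply(fix$nodes, build_node_lexicon)
  words <- c("yeast", "two", "hybrid", "gal4", "resonance", "plain")
  for (trial in 1:10) {
    body <- paste(sample(words, 8, replace = TRUE), collapse = " ")
    doc <- document_record("T", body = body)
    lex <- lexicons[[sample.int(length(lexicons), 1)]]
    f <- extract_pair_features(doc, lex, stats)
    for (grp in c("uni_concept", "bi_concept", "uni_synonym", "bi_synonym")) {
      expect_equal(f[[paste0("term_match_", grp)]],
                   as.numeric(f[[paste0("term_match_ratio_", grp)]] > 0))
    }
    # appending text never decreases any match/sum/ratio feature
    doc2 <- document_record("T2", body = paste(body, "two hybrid assay"))
    f2 <- extract_pair_features(doc2, lex, stats)
    grow <- grep("^(term_match|mi_sum|chi2_sum|perfect)", names(f))
    expect_true(all(f2[grow] >= f[grow] - 1e-12))
    # purity: identical inputs give identical vectors
    expect_identical(extract_pair_features(doc, lex, stats), f)
  }
})

test_that("nodes without synonyms yield zero synonym features, no NaN", {
  stats <- read_term_stats(ref_stats_path())
  lex <- build_node_lexicon(ontology_node("MI:0096", "pull down"))
  f <- extract_pair_features(
    document_record("D", body = "a pull down assay"), lex, stats)
  syn <- grep("synonym", names(f), value = TRUE)
  expect_true(all(f[syn] == 0))
  expect_false(anyNA(f))
})

test_that("popularity, regex hook and keyword presence flow through", {
  stats <- read_term_stats(ref_stats_path())
  ann <- list(D1 = c("MI:0018", "MI:0096"), D2 = "MI:0018",
              D3 = c("MI:0018", "MI:0018"))
  pop <- compute_node_popularity(ann)
  expect_equal(node_popularity_of(pop, "MI:0018"), 3L)  # set semantics
  expect_equal(node_popularity_of(pop, "MI:0096"), 1L)
  expect_equal(node_popularity_of(pop, "MI:0440"), 0L)

  node <- ontology_node("MI:0018", "two hybrid", keyword = "hybrid")
  lex <- build_node_lexicon(node)
  doc <- document_record("D9", body = "a hybrid approach")
  f <- extract_pair_features(doc, lex, stats, popularity = pop,
                             regex_hit = 1L)
  expect_equal(f[["node_popularity"]], 3)
  expect_equal(f[["regex_annotation"]], 1)
  expect_equal(f[["keyword_presence"]], 1)

  hook_path <- withr::local_tempfile()
  writeLines("MI:0018\ttwo[- ]hybrid", hook_path)
  hook <- read_regex_hook(hook_path)
  expect_equal(triagemap:::regex_hit_for(doc, "MI:0018", hook), 0L)
  doc2 <- document_record("DA", body = "Two-hybrid assays were used")
  expect_equal(triagemap:::regex_hit_for(doc2, "MI:0018", hook), 1L)
  expect_equal(triagemap:::regex_hit_for(doc2, "MI:0099", hook), 0L)
})

test_that("term statistics use the annotated-node class definition", {
  # balanced fixture: term unique to one node, annotated in half the docs
  nodes <- list(
    A = ontology_node("A", "alphaterm betaterm"),
    B = ontology_node("B", "gammaterm deltaterm"))
  docs <- list(
    document_record("D1", body = "alphaterm betaterm filler stuff"),
    document_record("D2", body = "alphaterm betaterm more filler"),
    document_record("D3", body = "gammaterm deltaterm filler stuff"),
    document_record("D4", body = "gammaterm deltaterm more filler"))
  corpus <- labeled_corpus(docs)
  ann <- list(D1 = "A", D2 = "A", D3 = "B", D4 = "B")
  lexicons <- lapply(nodes, build_node_lexicon)
  stats <- compute_term_statistics(corpus, ann, lexicons)
  # perfect association on the balanced fixture: MI = 1 bit, chi2 = n
  for (term in c("alphaterm", "gammaterm")) {
    expect_equal(stats$mi[stats$term == porter_stem(term)], 1.0)
    expect_equal(stats$chi2[stats$term == porter_stem(term)], 4.0)
  }
  expect_error(compute_term_statistics(corpus, list(), lexicons), "empty")
})
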