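test_that("pair-instance generation counts positives and negatives", {
  fix <- small_imt_fixture(n_docs = 2L, n_nodes = 10L, seed = 3L)
  assets <- imt_assets(fix)
  inst <- generate_pair_instances(fix$corpus, fix$annotations,
                                  assets$lexicons, assets$stats,
                                  assets$popularity, imt_config(seed = 1L))
  n_gold <- sum(lengths(fix$annotations))
  expect_equal(nrow(inst$features), 2L * 10L)
  expect_equal(sum(inst$labels), n_gold)
  expect_equal(sum(inst$labels == 0L), 2L * 10L - n_gold)

  # ratio mode: per-document negatives = R x positives, seed-reproducible
  cfg2 <- imt_config(negative_sampling = 2, seed = 11L)
  i1 <- generate_pair_instances(fix$corpus, fix$annotations,
                                assets$lexicons, assets$stats,
                                assets$popularity, cfg2)
  i2 <- generate_pair_instances(fix$corpus, fix$annotations,
                                assets$lexicons, assets$stats,
                                assets$popularity, cfg2)
  expect_identical(i1, i2)
  for (d in names(fix$annotations)) {
    npos <- length(fix$annotations[[d]])
    expect_equal(sum(i1$doc_id == d & i1$labels == 0L),
                 min(10L - npos, 2L * npos))
  }
  expect_error(generate_pair_instances(fix$corpus, fix$annotations,
                                       list(), assets$stats,
                                       assets$popularity, imt_config()),
               "empty")
})

test_that("chi-square selection ranks a perfectly aligned feature first", {
  set.seed(17)
  n <- 80L
  y <- rep(c(0L, 1L), n / 2)
  X <- matrix(stats::runif(n * 21), n, 21,
              dimnames = list(NULL, triagemap:::imt_feature_names()))
  X[, "perfect_match_concept"] <- y            # equals the label
  inst <- list(features = X, labels = y)
  sel <- select_pair_features(inst, 5L)
  expect_equal(sel[1], "perfect_match_concept")
  scores <- attr(sel, "scores")
  expect_equal(scores$score[scores$feature == "perfect_match_concept"],
               as.numeric(n))                  # chi2 = n at perfection
  expect_equal(select_pair_features(inst, 21L)[order(select_pair_features(inst, 21L))],
               sort(triagemap:::imt_feature_names()))
  expect_error(select_pair_features(inst, 0L), "\\[1, 21\\]")
  expect_error(select_pair_features(inst, 22L), "\\[1, 21\\]")
})

test_that("the ten mapping presets decode and train separably", {
  expect_length(imt_preset_names(), 10L)
  cfg <- imt_preset("rf-12")
  expect_equal(cfg$algorithm, "random_forest")
  expect_equal(cfg$n_features, 12L)
  expect_equal(imt_preset("nbt-7")$algorithm, "nb_tree")
  expect_equal(imt_preset("j48-14")$n_features, 14L)
  expect_error(imt_preset("zzz-3"), "valid presets")

  fix <- small_imt_fixture(n_docs = 14L, n_nodes = 5L, seed = 19L)
  assets <- imt_assets(fix)
  inst <- generate_pair_instances(fix$corpus, fix$annotations,
                                  assets$lexicons, assets$stats,
                                  assets$popularity, imt_config(seed = 2L))
  for (alg in c("j48", "random_forest", "random_committee", "nb_tree")) {
    model <- train_imt(inst, imt_config(algorithm = alg, seed = 2L))
    conf <- triagemap:::tree_ensemble_prob(model$model,
                                           inst$features[, model$features,
                                                         drop = FALSE])
    pred <- as.integer(conf >= 0.5)
    expect_equal(pred, inst$labels)   # training-set separability
  }
  expect_error(train_imt(list(features = inst$features,
                              labels = rep(1L, nrow(inst$features))),
                         imt_config()), "both classes")
})

test_that("same seed gives identical trained models and predictions", {
  fix <- small_imt_fixture(n_docs = 10L, n_nodes = 4L, seed = 23L)
  assets <- imt_assets(fix)
  inst <- generate_pair_instances(fix$corpus, fix$annotations,
                                  assets$lexicons, assets$stats,
                                  assets$popularity, imt_config(seed = 4L))
  m1 <- train_imt(inst, imt_config(algorithm = "random_forest", seed = 4L))
  m2 <- train_imt(inst, imt_config(algorithm = "random_forest", seed = 4L))
  expect_identical(m1, m2)
  doc <- corpus_documents(fix$corpus)[[1]]
  p1 <- predict_imt(m1, doc, assets$lexicons, assets$stats,
                    assets$popularity)
  p2 <- predict_imt(m2, doc, assets$lexicons, assets$stats,
                    assets$popularity)
  expect_identical(p1, p2)
  # sorted by confidence desc then node_id
  expect_true(all(diff(p1$confidence) <= 1e-12))
})

test_that("documents with no method mentions may yield zero annotations", {
  fix <- small_imt_fixture(n_docs = 16L, n_nodes = 5L, seed = 29L)
  assets <- imt_assets(fix)
  inst <- generate_pair_instances(fix$corpus, fix$annotations,
                                  assets$lexicons, assets$stats,
                                  assets$popularity, imt_config(seed = 1L))
  model <- train_imt(inst, imt_config(algorithm = "j48", seed = 1L))
  blank <- document_record("BLANK",
    body = "Unrelated filler prose. Nothing about methods here.")
  pred <- predict_imt(model, blank, assets$lexicons, assets$stats,
                      assets$popularity)
  expect_equal(sum(pred$label), 0L)
})

test_that("evidence sentence selection follows score, then length, then offset", {
  stats <- read_term_stats(ref_stats_path())
  lex <- build_node_lexicon(ontology_node("S1", "yeast two hybrid"))
  text <- paste("A hybrid construct was expressed.",
                "Some yeast cultures were grown overnight in rich medium.")
  sentences <- split_sentences(text)
  ev <- extract_evidence_sentence(sentences, lex, stats)
  # "hybrid" (1041.587496) outscores "yeast" (402.283) despite length
  expect_equal(ev$score, 1041.587496)
  expect_match(ev$sentence, "hybrid")

  # all-zero scores: the longest sentence wins
  lex0 <- build_node_lexicon(ontology_node("S2", "absentterm missing"))
  ev0 <- extract_evidence_sentence(sentences, lex0, stats)
  expect_equal(ev0$score, 0)
  expect_equal(ev0$sentence,
               sentences$sentence[which.max(nchar(sentences$sentence))])

  # one-sentence document returns it regardless of score
  one <- split_sentences("Nothing relevant at all.")
  expect_equal(extract_evidence_sentence(one, lex, stats)$sentence,
               "Nothing relevant at all.")
  # empty document
  ev_empty <- extract_evidence_sentence(split_sentences(""), lex, stats)
  expect_equal(ev_empty, list(sentence = "", score = 0))
})

test_that("evidence scores match a brute-force rescan on random fixtures", {
  stats <- read_term_stats(ref_stats_path())
  words <- c("yeast", "two", "hybrid", "resonance", "gal4", "plain", "text")
  set.seed(37)
  for (trial in 1:15) {
    n_sent <- sample(2:5, 1)
    sents <- vapply(seq_len(n_sent), function(i) {
      toks <- sample(words, sample(3:7, 1), replace = TRUE)
      paste0(toupper(substr(toks[1], 1, 1)),
             paste(c(substring(toks[1], 2), toks[-1]), collapse = " "), ".")
    }, character(1))
    text <- paste(sents, collapse = " ")
    sentences <- split_sentences(text)
    lex <- build_node_lexicon(ontology_node("R", "yeast two hybrid"))
    ev <- extract_evidence_sentence(sentences, lex, stats)
    # oracle: rescan every sentence independently
    oracle <- vapply(sentences$sentence, function(s) {
      toks <- unique(normalize_and_tokenize(s))
      sum(stats$chi2[stats$term %in% intersect(toks, c("yeast", "two", "hybrid"))])
    }, numeric(1), USE.NAMES = FALSE)
    expect_equal(ev$score, max(oracle))
    best_len <- max(nchar(sentences$sentence)[oracle == max(oracle)])
    expect_equal(nchar(ev$sentence), best_len)
  }
})
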