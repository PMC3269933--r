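test_that("triage corpus TSV round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("doc_id\tlabel\ttitle\tabstract",
               "A1\t1\tBinding study\tBRCA1 interacts with BARD1",
               "A2\t0\tUnrelated\tNothing to see",
               "A3\t\tUnlabeled\tTest article"), path)
  corpus <- read_act_corpus(path)
  expect_s3_class(corpus, "labeled_corpus")
  expect_length(corpus_documents(corpus), 3L)
  expect_equal(corpus$label_counts, c(`0` = 1L, `1` = 1L))
  expect_true(is.na(corpus_documents(corpus)[[3]]$gold_label))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_act_corpus(corpus, out)
  expect_identical(readLines(out), readLines(path))
})

test_that("triage corpus reader rejects duplicates and bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("doc_id\tlabel\ttitle\tabstract",
               "A1\t1\tx\ty", "A1\t0\tz\tw"), path)
  expect_error(read_act_corpus(path), "A1")
  writeLines(c("doc_id\tlabel\ttitle\tabstract",
               "A1\t7\tx\ty"), path)
  expect_error(read_act_corpus(path), "line 2")
})

test_that("full-text corpus reader maps files to documents", {
  dir <- withr::local_tempdir()
  writeLines("Alpha body text", file.path(dir, "A.txt"))
  writeLines("Beta body text", file.path(dir, "B.txt"))
  dir.create(file.path(dir, "nested"))
  writeLines("ignored", file.path(dir, "nested", "C.txt"))
  corpus <- read_fulltext_corpus(dir)
  expect_equal(corpus_ids(corpus), c("A", "B"))   # subdirectories ignored
  expect_equal(corpus_documents(corpus)[[1]]$body, "Alpha body text")
  expect_equal(corpus_documents(corpus)[[1]]$title, "")

  writeLines(character(0), file.path(dir, "empty.txt"))
  expect_error(read_fulltext_corpus(dir), "empty")
  expect_error(read_fulltext_corpus(withr::local_tempdir()), "no files")
})

test_that("OBO parsing extracts non-obsolete terms with synonyms", {
  nodes <- parse_obo(synthetic_obo_path())
  expect_false("MI:9999" %in% names(nodes))    # obsolete excluded
  expect_length(nodes, 6L)
  th <- nodes[["MI:0018"]]
  expect_equal(th$name, "two hybrid")
  expect_length(th$synonyms, 3L)
  # scope restriction drops the RELATED synonym
  exact_only <- parse_obo(synthetic_obo_path(), synonym_scopes = "EXACT")
  expect_length(exact_only[["MI:0018"]]$synonyms, 2L)
})

test_that("allowed-ID restriction reports missing IDs loudly", {
  expect_warning(
    nodes <- parse_obo(synthetic_obo_path(),
                       allowed_ids = c("MI:0018", "MI:0096", "MI:0001")),
    "MI:0001")
  expect_equal(names(nodes), c("MI:0018", "MI:0096"))
  expect_equal(attr(nodes, "missing_ids"), "MI:0001")
})

test_that("obo round-trip: N terms with K obsolete yield N-K nodes", {
  set.seed(21)
  for (trial in 1:3) {
    n <- sample(3:8, 1); k_obs <- sample(0:2, 1)
    nodes <- lapply(seq_len(n), function(i)
      ontology_node(sprintf("XX:%04d", i), paste("method", letters[i]),
                    synonyms = if (i %% 2) paste("alt", letters[i])))
    names(nodes) <- vapply(nodes, `[[`, "", "node_id")
    path <- withr::local_tempfile(fileext = ".obo")
    write_obo(nodes, path)
    if (k_obs > 0) {
      obs <- unlist(lapply(seq_len(k_obs), function(i)
        c("[Term]", sprintf("id: XX:9%03d", i), "name: dead",
          "is_obsolete: true", "")))
      cat(obs, file = path, sep = "\n", append = TRUE)
    }
    back <- parse_obo(path)
    expect_length(back, n)
    expect_equal(lapply(back, `[[`, "synonyms"),
                 lapply(nodes, `[[`, "synonyms"))
  }
})

test_that("lexicon supplement merges synonyms and keyword idempotently", {
  nodes <- parse_obo(synthetic_obo_path())
  supp <- read_lexicon_supplement(
    system.file("extdata", "example_supplement.tsv", package = "triagemap"))
  merged <- apply_lexicon_supplement(nodes, supp)
  expect_true("anti bait immunoprecipitation" %in%
                merged[["MI:0006"]]$synonyms)
  expect_true("radioligand binding" %in% merged[["MI:0440"]]$synonyms)
  expect_equal(merged[["MI:0006"]]$keyword, "coimmunoprecipitation")
  twice <- apply_lexicon_supplement(merged, supp)
  expect_identical(twice, merged)

  bad <- withr::local_tempfile()
  writeLines(c("node_id\tkind\tvalue", "MI:0006\tfrobnicate\tx"), bad)
  expect_error(read_lexicon_supplement(bad), "unknown supplement kind")
  writeLines(c("node_id\tkind\tvalue", "MI:0006\tkeyword\ttwo words"), bad)
  expect_error(read_lexicon_supplement(bad), "whitespace")
})

test_that("annotation sets round-trip with set semantics", {
  ann <- list(D2 = c("MI:0018", "MI:0096", "MI:0018"), D1 = "MI:0006")
  path <- withr::local_tempfile()
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back, list(D1 = "MI:0006", D2 = c("MI:0018", "MI:0096")))
  expect_error(read_annotations(path, allowed_nodes = "MI:0018"),
               "disallowed")
})

test_that("prediction writer enforces ranks, confidence bounds, tab safety", {
  path <- withr::local_tempfile()
  act <- data.frame(doc_id = c("B", "A", "C"), label = c(1L, 1L, 0L),
                    confidence = c(0.9, 0.7, 0.2))
  write_predictions(act, path, task = "act")
  lines <- readLines(path)
  expect_equal(lines[1], "doc_id\tlabel\tconfidence\trank")
  expect_equal(vapply(strsplit(lines[-1], "\t"), `[`, "", 4), c("1", "2", "3"))

  expect_error(write_predictions(transform(act, confidence = c(2, 0.5, 0.1)),
                                 path, task = "act"), "confidence")

  imt <- data.frame(doc_id = "D1", node_id = "MI:0018", confidence = 0.8,
                    evidence = "tab\there")
  write_predictions(imt, path, task = "imt")
  expect_equal(strsplit(readLines(path)[2], "\t")[[1]][4], "tab here")

  write_predictions(act[0, ], path, task = "act")
  expect_equal(readLines(path), "doc_id\tlabel\tconfidence\trank")
})
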