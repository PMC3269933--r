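#' Document and corpus containers
#'
#' A `document_record` holds one article: an opaque `doc_id`, a `title`
#' (may be empty; empty for full-text corpora), a `body` (abstract for
#' the triage task, full text for the ontology-mapping task) and an
#' optional binary `gold_label` (`NA` = unlabeled). A `labeled_corpus`
#' is an ordered list of records with cached label counts.
#'
#' @param doc_id non-empty string.
#' @param title,body text; at least one must be non-empty.
#' @param gold_label 0, 1 or `NA`.
#' @return `document_record` / `labeled_corpus` object.
#' @export
document_record <- function(doc_id, title = "", body = "",
                            gold_label = NA_integer_) {
  doc_id <- as.character(doc_id)
  if (length(doc_id) != 1L || is.na(doc_id) || !nzchar(doc_id))
    stop("doc_id must be a non-empty string")
  title <- if (is.na(title)) "" else as.character(title)
  body <- if (is.na(body)) "" else as.character(body)
  if (!nzchar(title) && !nzchar(body))
    stop("document '", doc_id, "': at least one of title/body must be non-empty")
  if (!is.na(gold_label) && !gold_label %in% c(0L, 1L))
    stop("gold_label must be 0, 1 or NA")
  structure(list(doc_id = doc_id, title = title, body = body,
                 gold_label = as.integer(gold_label)),
            class = "document_record")
}

#' @param documents list of `document_record`s with unique IDs.
#' @rdname document_record
#' @export
labeled_corpus <- function(documents) {
  ids <- vapply(documents, `[[`, character(1), "doc_id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate doc_id in corpus: ", dup[1])
  labels <- vapply(documents, `[[`, integer(1), "gold_label")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  structure(list(documents = documents,
                 label_counts = c(`0` = unname(counts["0"]),
                                  `1` = unname(counts["1"]))),
            class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat(sprintf("labeled_corpus: %d documents (pos %d / neg %d / unlabeled %d)\n",
              length(x$documents), x$label_counts[["1"]],
              x$label_counts[["0"]],
              length(x$documents) - sum(x$label_counts)))
  invisible(x)
}

#' Access corpus contents
#'
#' `corpus_documents()` returns the ordered list of `document_record`s,
#' `corpus_ids()` their IDs, and `document_text()` the text a pipeline
#' operates on (title and body concatenated).
#'
#' @param corpus a `labeled_corpus`.
#' @return list of records / character vector / character scalar.
#' @export
corpus_documents <- function(corpus) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  corpus$documents
}

#' @rdname corpus_documents
#' @export
corpus_ids <- function(corpus)
  vapply(corpus_documents(corpus), `[[`, character(1), "doc_id")

#' @param doc a `document_record`.
#' @rdname corpus_documents
#' @export
document_text <- function(doc) {
  if (nzchar(doc$title) && nzchar(doc$body))
    paste(doc$title, doc$body) else paste0(doc$title, doc$body)
}

#' Read a triage corpus from TSV
#'
#' Expected layout: header line then one row per article with columns
#' `doc_id`, `label` (0/1, empty = unlabeled), `title`, `abstract`.
#'
#' @param path TSV file path (UTF-8).
#' @return `labeled_corpus`.
#' @export
read_act_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty corpus file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c("doc_id", "label", "title", "abstract")
  if (!identical(header, expected))
    stop("corpus header must be: ", paste(expected, collapse = ", "))
  docs <- vector("list", length(lines) - 1L)
  for (i in seq_along(docs)) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    length(fields) <- 4L                    # pad trailing empties
    fields[is.na(fields)] <- ""
    if (!nzchar(fields[1]))
      stop("malformed corpus row at line ", i + 1L, ": empty doc_id")
    label <- fields[2]
    if (!label %in% c("", "0", "1"))
      stop("malformed corpus row at line ", i + 1L,
           ": label must be 0, 1 or empty, got '", label, "'")
    docs[[i]] <- document_record(
      fields[1], fields[3], fields[4],
      if (nzchar(label)) as.integer(label) else NA_integer_)
  }
  labeled_corpus(docs)
}

#' Write a triage corpus to TSV
#'
#' Inverse of [read_act_corpus()]; embedded tabs/newlines in text fields
#' are replaced by single spaces so the file round-trips.
#'
#' @param corpus `labeled_corpus`.
#' @param path output path.
#' @export
write_act_corpus <- function(corpus, path) {
  docs <- corpus_documents(corpus)
  clean <- function(x) gsub("[\t\r\n]+", " ", x)
  rows <- vapply(docs, function(d) {
    paste(d$doc_id,
          if (is.na(d$gold_label)) "" else d$gold_label,
          clean(d$title), clean(d$body), sep = "\t")
  }, character(1))
  writeLines(c("doc_id\tlabel\ttitle\tabstract", rows), path,
             useBytes = FALSE)
  invisible(path)
}

#' Read a full-text corpus from a directory
#'
#' Every regular file directly inside `dir` becomes one document whose
#' `doc_id` is the filename without extension and whose `body` is the
#' file contents; titles are left empty. Subdirectories are ignored.
#'
#' @param dir directory path.
#' @return `labeled_corpus` (all labels unset).
#' @export
read_fulltext_corpus <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in directory: ", dir)
  docs <- lapply(sort(files, method = "radix"), function(f) {
    body <- tryCatch(
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
      error = function(e) stop("unreadable file: ", f, " (", conditionMessage(e), ")"))
    if (!nzchar(trimws(body))) stop("empty document file: ", f)
    document_record(tools::file_path_sans_ext(basename(f)), body = body)
  })
  labeled_corpus(docs)
}

#' An ontology node
#'
#' @param node_id accession string (e.g. `"MI:0018"`).
#' @param name canonical concept name, non-empty.
#' @param synonyms character vector.
#' @param keyword optional single informative token (whitespace-free
#'   after normalization), or `NA`.
#' @return `ontology_node`.
#' @export
ontology_node <- function(node_id, name, synonyms = character(0),
                          keyword = NA_character_) {
  if (!nzchar(node_id)) stop("node_id must be non-empty")
  if (!nzchar(name)) stop("node '", node_id, "': name must be non-empty")
  if (!is.na(keyword)) {
    norm <- normalize_and_tokenize(keyword)
    if (length(norm) != 1L)
      stop("node '", node_id, "': keyword must normalize to a single token")
  }
  structure(list(node_id = node_id, name = name,
                 synonyms = unique(as.character(synonyms)),
                 keyword = as.character(keyword)),
            class = "ontology_node")
}

#' Parse an OBO 1.2 flat file into ontology nodes
#'
#' One node per non-obsolete `[Term]` stanza. Synonyms are taken from
#' `synonym:` lines; by default all scopes (EXACT/RELATED/NARROW/BROAD)
#' are ingested, restrictable via `synonym_scopes`. `exact_synonym:` /
#' `related_synonym:` legacy tags are also understood.
#'
#' @param path OBO file path.
#' @param allowed_ids optional character vector: restrict output to
#'   these IDs. IDs absent from the file are reported via a warning and
#'   in the `missing_ids` attribute of the result, never silently.
#' @param synonym_scopes scopes to keep, default all.
#' @return named list of `ontology_node` (names = node IDs), attribute
#'   `missing_ids`.
#' @export
parse_obo <- function(path, allowed_ids = NULL,
                      synonym_scopes = c("EXACT", "RELATED", "NARROW", "BROAD")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  term_starts <- which(trimws(lines) == "[Term]")
  stanza_starts <- which(grepl("^\\[", trimws(lines)))
  nodes <- list()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    stanza <- lines[(s + 1L):end]
    stanza <- stanza[nzchar(trimws(stanza))]
    get1 <- function(tag) {
      hits <- grep(paste0("^", tag, ":"), stanza, value = TRUE)
      if (!length(hits)) return(NA_character_)
      trimws(sub(paste0("^", tag, ":"), "", hits[1]))
    }
    id <- get1("id")
    if (is.na(id))
      stop("OBO stanza starting at line ", s, " has no id")
    if (identical(get1("is_obsolete"), "true")) next
    name <- get1("name")
    if (is.na(name) || !nzchar(name))
      stop("OBO term ", id, " has no name")
    syn_lines <- grep("^(synonym|exact_synonym|related_synonym):", stanza,
                      value = TRUE)
    synonyms <- character(0)
    for (sl in syn_lines) {
      m <- regmatches(sl, regexec('"([^"]*)"\\s*([A-Z]*)', sl))[[1]]
      if (length(m) < 2L)
        stop("unparseable synonym line in term ", id, ": ", sl)
      scope <- if (length(m) >= 3L && nzchar(m[3])) m[3] else "RELATED"
      if (scope %in% synonym_scopes) synonyms <- c(synonyms, m[2])
    }
    nodes[[id]] <- ontology_node(id, name, synonyms)
  }
  missing_ids <- character(0)
  if (!is.null(allowed_ids)) {
    missing_ids <- setdiff(allowed_ids, names(nodes))
    if (length(missing_ids))
      warning("allowed IDs absent from OBO file: ",
              paste(missing_ids, collapse = ", "))
    nodes <- nodes[intersect(allowed_ids, names(nodes))]
  }
  attr(nodes, "missing_ids") <- missing_ids
  nodes
}

#' Write ontology nodes to an OBO 1.2 file
#'
#' Minimal serializer used by the synthetic-fixture generator so that
#' integration tests exercise the real parser; all synonyms are written
#' with EXACT scope.
#'
#' @param nodes named list of `ontology_node`.
#' @param path output path.
#' @export
write_obo <- function(nodes, path) {
  out <- c("format-version: 1.2", "")
  for (nd in nodes) {
    out <- c(out, "[Term]", paste0("id: ", nd$node_id),
             paste0("name: ", nd$name),
             vapply(nd$synonyms,
                    function(s) sprintf('synonym: "%s" EXACT []', s),
                    character(1)),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a lexicon supplement (manually added synonyms and keywords)
#'
#' TSV with columns `node_id`, `kind` (`synonym` or `keyword`), `value`.
#' Use [apply_lexicon_supplement()] to merge into parsed nodes.
#'
#' @param path TSV path.
#' @return data.frame with columns `node_id`, `kind`, `value`.
#' @export
read_lexicon_supplement <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = "character")
  if (!all(c("node_id", "kind", "value") %in% names(df)))
    stop("supplement must have columns node_id, kind, value")
  bad <- setdiff(unique(df$kind), c("synonym", "keyword"))
  if (length(bad))
    stop("unknown supplement kind: ", paste(bad, collapse = ", "))
  kw <- df$value[df$kind == "keyword"]
  if (any(grepl("[[:space:]]", kw)))
    stop("keyword with internal whitespace: ",
         paste(kw[grepl("[[:space:]]", kw)], collapse = ", "))
  df
}

#' Merge a lexicon supplement into ontology nodes
#'
#' Synonyms are appended (deduplicated); a keyword row overwrites any
#' prior keyword for that node. Applying the same supplement twice is a
#' no-op (idempotent).
#'
#' @param nodes named list of `ontology_node`.
#' @param supplement data.frame from [read_lexicon_supplement()].
#' @return updated node list.
#' @export
apply_lexicon_supplement <- function(nodes, supplement) {
  for (i in seq_len(nrow(supplement))) {
    id <- supplement$node_id[i]
    if (!id %in% names(nodes))
      stop("supplement refers to unknown node: ", id)
    nd <- nodes[[id]]
    if (supplement$kind[i] == "synonym") {
      nd$synonyms <- unique(c(nd$synonyms, supplement$value[i]))
    } else {
      nd <- ontology_node(nd$node_id, nd$name, nd$synonyms,
                          supplement$value[i])
    }
    nodes[[id]] <- nd
  }
  nodes
}

#' Read / write document-to-node annotation sets
#'
#' An annotation set maps `doc_id` to a set of `node_id`s; the file
#' layout is one `doc_id TAB node_id` pair per line, no header.
#' Duplicate pairs collapse (set semantics).
#'
#' @param path TSV path.
#' @param allowed_nodes optional character vector; any annotation to a
#'   node outside it is an error.
#' @return named list of character vectors (names = doc IDs, values =
#'   sorted node IDs).
#' @export
read_annotations <- function(path, allowed_nodes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  ann <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L || !all(nzchar(fields)))
      stop("malformed annotation at line ", i, ": ", lines[i])
    if (!is.null(allowed_nodes) && !fields[2] %in% allowed_nodes)
      stop("annotation to disallowed node '", fields[2], "' at line ", i)
    ann[[fields[1]]] <- c(ann[[fields[1]]], fields[2])
  }
  lapply(ann, function(x) sort(unique(x), method = "radix"))
}

#' @param annotations named list as returned by [read_annotations()].
#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  ids <- sort(names(annotations), method = "radix")
  rows <- unlist(lapply(ids, function(d)
    paste(d, sort(unique(annotations[[d]]), method = "radix"), sep = "\t")),
    use.names = FALSE)
  writeLines(if (is.null(rows)) character(0) else rows, path)
  invisible(path)
}

#' Write ranked predictions to TSV
#'
#' For the triage task (`task = "act"`) the columns are `doc_id`,
#' `label`, `confidence`, `rank`; the rank column is strictly
#' increasing. For the mapping task (`task = "imt"`) the columns are
#' `doc_id`, `node_id`, `confidence`, `evidence`; any tab or newline
#' inside the evidence sentence is replaced by a single space so the
#' file stays well-formed TSV.
#'
#' @param records data.frame of predictions (see column lists above;
#'   rank is assigned here from row order for ACT).
#' @param path output path.
#' @param task `"act"` or `"imt"`.
#' @export
write_predictions <- function(records, path, task = c("act", "imt")) {
  task <- match.arg(task)
  if (nrow(records) && (any(records$confidence < 0) ||
                        any(records$confidence > 1)))
    stop("confidence outside [0,1]")
  if (task == "act") {
    header <- "doc_id\tlabel\tconfidence\trank"
    rows <- if (nrow(records)) {
      paste(records$doc_id, records$label,
            sprintf("%.6f", records$confidence),
            seq_len(nrow(records)), sep = "\t")
    } else character(0)
  } else {
    header <- "doc_id\tnode_id\tconfidence\tevidence"
    clean <- function(x) gsub("[\t\r\n]+", " ", x)
    rows <- if (nrow(records)) {
      paste(records$doc_id, records$node_id,
            sprintf("%.6f", records$confidence),
            clean(records$evidence), sep = "\t")
    } else character(0)
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read back a predictions TSV written by [write_predictions()]
#'
#' @param path TSV path.
#' @param task `"act"` or `"imt"`.
#' @return data.frame.
#' @export
read_predictions <- function(path, task = c("act", "imt")) {
  task <- match.arg(task)
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- if (task == "act") c("doc_id", "label", "confidence", "rank")
          else c("doc_id", "node_id", "confidence", "evidence")
  if (!all(need %in% names(df)))
    stop("prediction file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$doc_id <- as.character(df$doc_id)
  if (task == "imt") df$node_id <- as.character(df$node_id)
  df
}
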