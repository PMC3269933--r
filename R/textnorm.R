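#' Normalize raw text into a token sequence
#'
#' Applies the shared normalization pipeline used by both the triage and
#' the ontology-mapping tasks: lowercase, replace punctuation by spaces,
#' split on whitespace, drop purely numeric tokens, and Porter-stem every
#' surviving token.
#'
#' Punctuation means the ASCII punctuation set plus the general Unicode
#' punctuation category; it is replaced by spaces (not deleted) so that
#' hyphenated forms such as "two-hybrid" tokenize into two tokens.
#' Tokens consisting solely of digits are removed; alphanumeric tokens
#' such as "gal4" are kept.
#'
#' @param text a character scalar (may be empty or `NA`).
#' @return character vector of normalized stems (possibly empty).
#' @examples
#' normalize_and_tokenize("Interaction of BRCA1")
#' @export
normalize_and_tokenize <- function(text) {
  if (length(text) != 1L) stop("`text` must be a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[[:punct:]]|\\p{P}|\\p{S}", " ", x, perl = TRUE)
  tokens <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens) & !grepl("^[0-9]+$", tokens)]
  if (!length(tokens)) return(character(0))
  porter_stem(tokens)
}

#' Extract unigrams and bigrams from a token sequence
#'
#' @param tokens character vector of normalized tokens.
#' @param orders integer vector, subset of `c(1, 2)`: which n-gram orders
#'   to emit. Unigrams come first in token order, then bigrams of
#'   consecutive tokens joined by a single space.
#' @return character vector of n-grams.
#' @export
extract_ngrams <- function(tokens, orders = c(1L, 2L)) {
  orders <- as.integer(orders)
  if (!length(orders) || !all(orders %in% c(1L, 2L)))
    stop("`orders` must be a non-empty subset of c(1, 2)")
  out <- character(0)
  if (1L %in% orders) out <- c(out, tokens)
  if (2L %in% orders && length(tokens) >= 2L) {
    n <- length(tokens)
    out <- c(out, paste(tokens[-n], tokens[-1L]))
  }
  out
}

# Abbreviations that do not end a sentence even when followed by
# whitespace and an uppercase letter or digit.
tm_abbreviations <- c("fig", "figs", "et al", "e.g", "i.e", "cf", "vs",
                      "dr", "mr", "mrs", "ms", "no", "nos", "ref", "refs",
                      "approx", "ca", "etc")

#' Split raw text into sentences
#'
#' Rule-based splitter: a sentence boundary is a run of `.`, `!` or `?`
#' followed by whitespace and an uppercase letter or digit, unless the
#' period terminates a known abbreviation (for example "Fig." or
#' "et al."). Character offsets into the original text are preserved.
#'
#' @param text a character scalar.
#' @return data.frame with columns `sentence`, `start`, `end` (1-based
#'   inclusive character offsets into `text`).
#' @export
split_sentences <- function(text) {
  empty <- data.frame(sentence = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (length(text) != 1L) stop("`text` must be a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  m <- gregexpr("[.!?]+(?=[[:space:]]+[[:upper:]0-9])", text, perl = TRUE)[[1]]
  boundaries <- integer(0)
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      prefix <- substr(text, max(1L, e - 12L), e - 1L)
      word <- regmatches(prefix, regexpr("[A-Za-z.]+( al)?$", prefix))
      is_abbrev <- length(word) == 1L &&
        tolower(word) %in% tm_abbreviations
      if (!is_abbrev) boundaries <- c(boundaries, e)
    }
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, nchar(text))
  out <- empty
  for (i in seq_along(starts)) {
    raw <- substr(text, starts[i], ends[i])
    lead <- nchar(raw) - nchar(sub("^[[:space:]]+", "", raw))
    trail <- nchar(raw) - nchar(sub("[[:space:]]+$", "", raw))
    s <- starts[i] + lead
    e <- ends[i] - trail
    if (e >= s) {
      out <- rbind(out, data.frame(sentence = substr(text, s, e),
                                   start = s, end = e,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
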