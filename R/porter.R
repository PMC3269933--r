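#' Porter stemming algorithm
#'
#' Reduces English words to their stems using the original 1980 Porter
#' suffix-stripping algorithm (steps 1a--5b, with the measure-based
#' conditions of the published definition). Tokens shorter than three
#' characters or containing any character outside `a`--`z` (for example
#' alphanumerics such as `"gal4"`) are returned unchanged.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("interaction", "phosphorylation", "regulation"))
#' @export
porter_stem <- function(words) {
  if (!is.character(words)) stop("`words` must be a character vector")
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

# --- single-word stemmer -------------------------------------------------

porter_stem1 <- function(word) {
  if (is.na(word) || nchar(word) <= 2L || grepl("[^a-z]", word)) return(word)
  word <- pt_step1a(word)
  word <- pt_step1b(word)
  word <- pt_step1c(word)
  word <- pt_step2(word)
  word <- pt_step3(word)
  word <- pt_step4(word)
  word <- pt_step5a(word)
  pt_step5b(word)
}

# Consonant test: not a,e,i,o,u; 'y' is a vowel when preceded by a
# consonant, a consonant at word start or after a vowel.
pt_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!pt_is_cons(chars, i - 1L))
  }
  TRUE
}

pt_cons_mask <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(logical(0))
  mask <- logical(n)
  for (i in seq_len(n)) mask[i] <- pt_is_cons(chars, i)
  mask
}

# m = number of VC sequences in the [C](VC)^m[V] form of the stem.
pt_measure <- function(stem) {
  mask <- pt_cons_mask(stem)
  if (length(mask) == 0L) return(0L)
  runs <- rle(mask)$values       # TRUE = consonant run
  m <- 0L
  seen_vowel <- FALSE
  for (r in runs) {
    if (!r) seen_vowel <- TRUE
    else if (seen_vowel) { m <- m + 1L; seen_vowel <- FALSE }
  }
  m
}

pt_has_vowel <- function(stem) any(!pt_cons_mask(stem))

pt_ends_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  a <- substr(stem, n - 1L, n - 1L)
  b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  mask <- pt_cons_mask(stem)
  mask[n]
}

# *o: stem ends consonant-vowel-consonant and final consonant is not w,x,y
pt_ends_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  mask <- pt_cons_mask(stem)
  if (!(mask[n - 2L] && !mask[n - 1L] && mask[n])) return(FALSE)
  !(substr(stem, n, n) %in% c("w", "x", "y"))
}

pt_ends_with <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n > k && substr(word, n - k + 1L, n) == suffix
}

pt_chop <- function(word, k) substr(word, 1L, nchar(word) - k)

pt_step1a <- function(w) {
  if (pt_ends_with(w, "sses")) return(pt_chop(w, 2L))
  if (pt_ends_with(w, "ies"))  return(pt_chop(w, 2L))
  if (pt_ends_with(w, "ss"))   return(w)
  if (pt_ends_with(w, "s"))    return(pt_chop(w, 1L))
  w
}

pt_step1b <- function(w) {
  if (pt_ends_with(w, "eed")) {
    stem <- pt_chop(w, 3L)
    if (pt_measure(stem) > 0L) return(pt_chop(w, 1L))
    return(w)
  }
  stripped <- FALSE
  if (pt_ends_with(w, "ed") && pt_has_vowel(pt_chop(w, 2L))) {
    w <- pt_chop(w, 2L); stripped <- TRUE
  } else if (pt_ends_with(w, "ing") && pt_has_vowel(pt_chop(w, 3L))) {
    w <- pt_chop(w, 3L); stripped <- TRUE
  }
  if (stripped) {
    if (pt_ends_with(w, "at") || pt_ends_with(w, "bl") || pt_ends_with(w, "iz")) {
      w <- paste0(w, "e")
    } else if (pt_ends_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- pt_chop(w, 1L)
    } else if (pt_measure(w) == 1L && pt_ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

pt_step1c <- function(w) {
  if (pt_ends_with(w, "y") && pt_has_vowel(pt_chop(w, 1L)))
    return(paste0(pt_chop(w, 1L), "i"))
  w
}

# Rule tables for steps 2-4; within a step the longest matching suffix is
# the one considered (lists are ordered longest-first).
pt_rules2 <- list(
  c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("biliti", "ble"),
  c("tional", "tion"), c("ation", "ate"), c("alism", "al"),
  c("entli", "ent"), c("ousli", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("ator", "ate"), c("eli", "e")
)

pt_rules3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"),
  c("iciti", "ic"), c("ical", "ic"), c("ness", ""), c("ful", "")
)

pt_rules4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
               "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
               "al", "er", "ic", "ou")

pt_apply_rules <- function(w, rules, min_m) {
  for (rule in rules) {
    if (pt_ends_with(w, rule[1])) {
      stem <- pt_chop(w, nchar(rule[1]))
      if (pt_measure(stem) > min_m) return(paste0(stem, rule[2]))
      return(w)   # longest match decides; condition failed -> stop
    }
  }
  w
}

pt_step2 <- function(w) pt_apply_rules(w, pt_rules2, 0L)
pt_step3 <- function(w) pt_apply_rules(w, pt_rules3, 0L)

pt_step4 <- function(w) {
  for (suf in pt_rules4) {
    if (pt_ends_with(w, suf)) {
      stem <- pt_chop(w, nchar(suf))
      if (pt_measure(stem) > 1L) {
        if (suf == "ion" &&
            !(substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")))
          return(w)
        return(stem)
      }
      return(w)
    }
  }
  w
}

pt_step5a <- function(w) {
  if (pt_ends_with(w, "e")) {
    stem <- pt_chop(w, 1L)
    m <- pt_measure(stem)
    if (m > 1L || (m == 1L && !pt_ends_cvc(stem))) return(stem)
  }
  w
}

pt_step5b <- function(w) {
  if (pt_measure(w) > 1L && pt_ends_double_cons(w) &&
      pt_ends_with(w, "l"))
    return(pt_chop(w, 1L))
  w
}
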