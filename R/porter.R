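#' Porter stem of a word
#'
#' Implements the classic Porter suffix-stripping algorithm (original rule
#' tables). Stemming collapses inflected forms onto one key, so that e.g.
#' "induces", "inducer" and "induce" all match a single effect-lexicon entry
#' "induc". Output is always lower case; words of fewer than three letters
#' are returned unchanged (conventional guard, since the measure-based rules
#' cannot apply to them).
#'
#' @param words character vector of single tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("induces", "inducer", "apoptosis", "acid"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

# ---- internals -------------------------------------------------------------

# consonant/vowel classification: y is a consonant at position 1 or after a
# vowel, a vowel after a consonant
porter_cv <- function(chars) {
  n <- length(chars)
  cv <- character(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    cv[i] <- if (ch %in% c("a", "e", "i", "o", "u")) {
      "v"
    } else if (ch == "y") {
      if (i == 1L || cv[i - 1L] == "v") "c" else "v"
    } else {
      "c"
    }
  }
  cv
}

# m in [C](VC){m}[V]
porter_m <- function(word) {
  if (nchar(word) == 0L) return(0L)
  cv <- porter_cv(strsplit(word, "", fixed = TRUE)[[1]])
  runs <- rle(cv)$values
  sum(runs == "v") - if (runs[length(runs)] == "v") 1L else 0L
}

porter_has_vowel <- function(word) {
  if (nchar(word) == 0L) return(FALSE)
  any(porter_cv(strsplit(word, "", fixed = TRUE)[[1]]) == "v")
}

porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  chars[n] == chars[n - 1L] && porter_cv(chars)[n] == "c"
}

# *o condition: ends cvc where the final consonant is not w, x or y
porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  cv <- porter_cv(chars)
  cv[n - 2L] == "c" && cv[n - 1L] == "v" && cv[n] == "c" &&
    !(chars[n] %in% c("w", "x", "y"))
}

ends_with <- function(word, suffix) {
  nw <- nchar(word)
  ns <- nchar(suffix)
  nw >= ns && substr(word, nw - ns + 1L, nw) == suffix
}

chop <- function(word, n) substr(word, 1L, nchar(word) - n)

# suffix tables; within a step only the longest matching suffix is considered
porter_step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
  c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
  c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)

porter_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

porter_step4_suffixes <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

porter_replace_longest <- function(word, rules, min_m = 1L) {
  best <- NULL
  for (r in rules) {
    if (ends_with(word, r[1]) && (is.null(best) || nchar(r[1]) > nchar(best[1]))) {
      best <- r
    }
  }
  if (is.null(best)) return(word)
  stem <- chop(word, nchar(best[1]))
  if (porter_m(stem) >= min_m) paste0(stem, best[2]) else word
}

porter_stem1 <- function(word) {
  w <- tolower(word)
  if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)

  # step 1a
  if (ends_with(w, "sses")) {
    w <- chop(w, 2L)
  } else if (ends_with(w, "ies")) {
    w <- chop(w, 2L)
  } else if (!ends_with(w, "ss") && ends_with(w, "s")) {
    w <- chop(w, 1L)
  }

  # step 1b
  if (ends_with(w, "eed")) {
    if (porter_m(chop(w, 3L)) > 0L) w <- chop(w, 1L)
  } else {
    fired <- FALSE
    if (ends_with(w, "ed") && porter_has_vowel(chop(w, 2L))) {
      w <- chop(w, 2L); fired <- TRUE
    } else if (ends_with(w, "ing") && porter_has_vowel(chop(w, 3L))) {
      w <- chop(w, 3L); fired <- TRUE
    }
    if (fired) {
      if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
        w <- paste0(w, "e")
      } else if (porter_double_cons(w) &&
                 !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
        w <- chop(w, 1L)
      } else if (porter_m(w) == 1L && porter_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (ends_with(w, "y") && porter_has_vowel(chop(w, 1L))) {
    w <- paste0(chop(w, 1L), "i")
  }

  # steps 2 and 3 (condition m > 0 on the stem)
  w <- porter_replace_longest(w, porter_step2_rules, min_m = 1L)
  w <- porter_replace_longest(w, porter_step3_rules, min_m = 1L)

  # step 4 (condition m > 1; ION additionally requires stem ending s or t)
  best <- ""
  for (s in porter_step4_suffixes) {
    if (ends_with(w, s) && nchar(s) > nchar(best)) best <- s
  }
  if (nchar(best) > 0L) {
    stem <- chop(w, nchar(best))
    if (porter_m(stem) > 1L &&
        (best != "ion" || ends_with(stem, "s") || ends_with(stem, "t"))) {
      w <- stem
    }
  }

  # step 5a
  if (ends_with(w, "e")) {
    stem <- chop(w, 1L)
    m <- porter_m(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) w <- stem
  }

  # step 5b
  if (porter_m(w) > 1L && porter_double_cons(w) && ends_with(w, "l")) {
    w <- chop(w, 1L)
  }

  w
}
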