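# Porter stemming algorithm (Porter 1980), used to build the stemmed variant
# of the event trigger lexicons. Implemented from the algorithm definition;
# behaviour is checked against the worked examples given there.

.pt_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_is_cons(chars, i - 1L))
  }
  TRUE
}

.pt_cons_flags <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  vapply(seq_along(chars), function(i) .pt_is_cons(chars, i), logical(1))
}

# measure m: number of VC blocks in [C](VC)^m[V]
.pt_measure <- function(word) {
  if (!nzchar(word)) return(0L)
  runs <- rle(.pt_cons_flags(word))$values
  if (length(runs) && runs[1]) runs <- runs[-1]
  as.integer(length(runs) %/% 2L)
}

.pt_has_vowel <- function(word) {
  nzchar(word) && any(!.pt_cons_flags(word))
}

.pt_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  a == b && .pt_cons_flags(word)[n]
}

# *o condition: stem ends cvc where the final c is not w, x or y
.pt_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  f <- .pt_cons_flags(word)
  last <- substr(word, n, n)
  f[n - 2L] && !f[n - 1L] && f[n] && !(last %in% c("w", "x", "y"))
}

.pt_ends <- function(word, suffix) {
  n <- nchar(word)
  k <- nchar(suffix)
  n > k && substring(word, n - k + 1L, n) == suffix
}

.pt_chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# rule tables for steps 2-4: suffix -> replacement, longest suffix first
.pt_step2 <- c(
  ational = "ate", ization = "ize", iveness = "ive", fulness = "ful",
  ousness = "ous", biliti = "ble", tional = "tion", entli = "ent",
  ousli = "ous", ation = "ate", alism = "al", aliti = "al", iviti = "ive",
  enci = "ence", anci = "ance", izer = "ize", abli = "able", alli = "al",
  ator = "ate", eli = "e", bli = "ble"
)
.pt_step3 <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic",
  ical = "ic", ful = "", ness = ""
)
.pt_step4 <- c(
  "ement", "ance", "ence", "able", "ible", "ment", "ant", "ent", "ion",
  "ism", "ate", "iti", "ous", "ive", "ize", "al", "er", "ic", "ou"
)

.pt_stem1 <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # step 1a
  if (.pt_ends(word, "sses")) {
    word <- .pt_chop(word, 2L)
  } else if (.pt_ends(word, "ies")) {
    word <- .pt_chop(word, 2L)
  } else if (!.pt_ends(word, "ss") && .pt_ends(word, "s")) {
    word <- .pt_chop(word, 1L)
  }

  # step 1b
  flag <- FALSE
  if (.pt_ends(word, "eed")) {
    if (.pt_measure(.pt_chop(word, 3L)) > 0L) word <- .pt_chop(word, 1L)
  } else if (.pt_ends(word, "ed") && .pt_has_vowel(.pt_chop(word, 2L))) {
    word <- .pt_chop(word, 2L)
    flag <- TRUE
  } else if (.pt_ends(word, "ing") && .pt_has_vowel(.pt_chop(word, 3L))) {
    word <- .pt_chop(word, 3L)
    flag <- TRUE
  }
  if (flag) {
    if (.pt_ends(word, "at") || .pt_ends(word, "bl") || .pt_ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.pt_double_cons(word) &&
               !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z"))) {
      word <- .pt_chop(word, 1L)
    } else if (.pt_measure(word) == 1L && .pt_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c
  if (.pt_ends(word, "y") && .pt_has_vowel(.pt_chop(word, 1L))) {
    word <- paste0(.pt_chop(word, 1L), "i")
  }

  # steps 2 and 3
  for (tab in list(.pt_step2, .pt_step3)) {
    for (suf in names(tab)) {
      if (.pt_ends(word, suf)) {
        stem <- .pt_chop(word, nchar(suf))
        if (.pt_measure(stem) > 0L) word <- paste0(stem, tab[[suf]])
        break
      }
    }
  }

  # step 4
  for (suf in .pt_step4) {
    if (.pt_ends(word, suf)) {
      stem <- .pt_chop(word, nchar(suf))
      if (suf == "ion" &&
          !(substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))) {
        next  # ion only removed after s or t
      }
      if (.pt_measure(stem) > 1L) word <- stem
      break
    }
  }

  # step 5a
  if (.pt_ends(word, "e")) {
    stem <- .pt_chop(word, 1L)
    m <- .pt_measure(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) word <- stem
  }
  # step 5b
  if (.pt_measure(word) > 1L && .pt_double_cons(word) &&
      .pt_ends(word, "l")) {
    word <- .pt_chop(word, 1L)
  }
  word
}

#' Porter stem of words
#'
#' Applies the Porter suffix-stripping algorithm, used when building the
#' stemmed event trigger lexicons and when deriving lexicon lookups for a
#' token. Input is lower-cased first.
#'
#' @param words character vector.
#' @return character vector of stems, same length.
#' @examples
#' porter_stem(c("expression", "expressed", "caresses", "ponies"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(words), .pt_stem1, character(1), USE.NAMES = FALSE)
}
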