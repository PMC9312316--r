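## Porter stemmer, implemented from the original algorithm description.
## One deliberate revision: step 1c rewrites a trailing "y" to "i" only when
## it is preceded by a consonant and the remaining stem has length > 1
## ("stay" -> "stay", "happy" -> "happi"); the original vowel-in-stem
## condition would stem "stay" to "stai", which mangles common short words.

.porter_is_cons <- function(ch, i, chs) {
  c <- chs[i]
  if (c %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (c == "y") {
    if (i == 1L) return(TRUE)
    return(!.porter_is_cons(ch, i - 1L, chs))
  }
  TRUE
}

# measure m: number of vowel-consonant sequences in the stem
.porter_m <- function(stem) {
  if (!nchar(stem)) return(0L)
  chs <- strsplit(stem, "", fixed = TRUE)[[1]]
  types <- vapply(seq_along(chs), function(i) .porter_is_cons(chs, i, chs),
                  logical(1))
  m <- 0L
  prev <- TRUE  # pretend leading consonant state
  seen_vowel <- FALSE
  for (tp in types) {
    if (!tp) seen_vowel <- TRUE
    if (tp && seen_vowel) { m <- m + 1L; seen_vowel <- FALSE }
  }
  m
}

.porter_has_vowel <- function(stem) {
  if (!nchar(stem)) return(FALSE)
  chs <- strsplit(stem, "", fixed = TRUE)[[1]]
  any(!vapply(seq_along(chs), function(i) .porter_is_cons(chs, i, chs),
              logical(1)))
}

.porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  a <- substr(word, n - 1, n - 1); b <- substr(word, n, n)
  if (a != b) return(FALSE)
  chs <- strsplit(word, "", fixed = TRUE)[[1]]
  .porter_is_cons(chs, n, chs)
}

# *o: stem ends cvc where the final c is not w, x or y
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  chs <- strsplit(word, "", fixed = TRUE)[[1]]
  if (!.porter_is_cons(chs, n, chs)) return(FALSE)
  if (.porter_is_cons(chs, n - 1L, chs)) return(FALSE)
  if (!.porter_is_cons(chs, n - 2L, chs)) return(FALSE)
  !(chs[n] %in% c("w", "x", "y"))
}

.ends <- function(word, suf) {
  n <- nchar(word); k <- nchar(suf)
  n >= k && substr(word, n - k + 1, n) == suf
}
.chop <- function(word, k) substr(word, 1, nchar(word) - k)

# ordered suffix rules for steps 2-4: list(suffix, replacement)
.porter_step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble"))
.porter_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", ""))
.porter_step4_sufs <- c("al", "ance", "ence", "er", "ic", "able", "ible",
  "ant", "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous",
  "ive", "ize")

.porter_one <- function(word) {
  if (nchar(word) <= 2) return(word)

  ## step 1a
  if (.ends(word, "sses")) word <- paste0(.chop(word, 4), "ss")
  else if (.ends(word, "ies")) word <- paste0(.chop(word, 3), "i")
  else if (.ends(word, "ss")) word <- word
  else if (.ends(word, "s")) word <- .chop(word, 1)

  ## step 1b
  flag1b <- FALSE
  if (.ends(word, "eed")) {
    if (.porter_m(.chop(word, 3)) > 0) word <- .chop(word, 1)
  } else if (.ends(word, "ed") && .porter_has_vowel(.chop(word, 2))) {
    word <- .chop(word, 2); flag1b <- TRUE
  } else if (.ends(word, "ing") && .porter_has_vowel(.chop(word, 3))) {
    word <- .chop(word, 3); flag1b <- TRUE
  }
  if (flag1b) {
    if (.ends(word, "at") || .ends(word, "bl") || .ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.porter_double_cons(word) &&
               !(.ends(word, "l") || .ends(word, "s") || .ends(word, "z"))) {
      word <- .chop(word, 1)
    } else if (.porter_m(word) == 1 && .porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  ## step 1c (revised rule, see header comment)
  if (.ends(word, "y")) {
    stem <- .chop(word, 1)
    if (nchar(stem) > 1) {
      chs <- strsplit(stem, "", fixed = TRUE)[[1]]
      if (.porter_is_cons(chs, length(chs), chs))
        word <- paste0(stem, "i")
    }
  }

  ## step 2
  for (r in .porter_step2_rules) {
    if (.ends(word, r[1])) {
      stem <- .chop(word, nchar(r[1]))
      if (.porter_m(stem) > 0) word <- paste0(stem, r[2])
      break
    }
  }

  ## step 3
  for (r in .porter_step3_rules) {
    if (.ends(word, r[1])) {
      stem <- .chop(word, nchar(r[1]))
      if (.porter_m(stem) > 0) word <- paste0(stem, r[2])
      break
    }
  }

  ## step 4
  for (suf in .porter_step4_sufs) {
    if (.ends(word, suf)) {
      stem <- .chop(word, nchar(suf))
      if (.porter_m(stem) > 1) {
        if (suf == "ion" &&
            !(.ends(stem, "s") || .ends(stem, "t"))) break
        word <- stem
      }
      break
    }
  }

  ## step 5a
  if (.ends(word, "e")) {
    stem <- .chop(word, 1)
    m <- .porter_m(stem)
    if (m > 1 || (m == 1 && !.porter_cvc(stem))) word <- stem
  }
  ## step 5b
  if (.porter_m(word) > 1 && .porter_double_cons(word) && .ends(word, "l"))
    word <- .chop(word, 1)

  word
}

#' Porter-stem a vector of lowercase tokens
#'
#' The classic rule-based suffix stripper, with one revision to the trailing
#' "y" rule (rewritten to "i" only after a consonant) so that short words
#' like "stay" survive intact. Tokens containing non-letters (digits,
#' placeholder tokens such as "xurl") are returned unchanged.
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of stems, same length and order.
#' @examples
#' porterStem(c("caresses", "ponies", "relational", "happy", "stay"))
#' @export
porterStem <- function(tokens) {
  if (!length(tokens)) return(character())
  out <- tokens
  pure <- grepl("^[a-z]+$", tokens)
  out[pure] <- vapply(tokens[pure], .porter_one, character(1),
                      USE.NAMES = FALSE)
  out
}
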