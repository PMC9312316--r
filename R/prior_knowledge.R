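## Lexicon-and-rules sentiment scoring: the expert-knowledge channel that
## feeds the informed sentiment classifier. Scoring operates on RAW text
## (casing and punctuation carry signal for the rules), not on the
## preprocessed token stream.

#' Construct or read a sentiment lexicon
#'
#' The lexicon file is tab-separated \code{term \\t valence} (the common
#' lexicon dialect); boosters are \code{term \\t factor}; negators one term
#' per line. The bundled files are small synthetic stand-ins used by the
#' test corpus generators, not a real lexicon.
#'
#' @param valencePath path to the term/valence TSV.
#' @param boosterPath optional path to the booster TSV (or NULL).
#' @param negatorPath optional path to the negator list (or NULL).
#' @return a \code{\link{SentimentLexicon}}.
#' @export
readLexicon <- function(valencePath,
                        boosterPath = NULL, negatorPath = NULL) {
  v <- utils::read.delim(valencePath, header = FALSE,
                         stringsAsFactors = FALSE)
  valence <- stats::setNames(as.numeric(v[[2]]), tolower(v[[1]]))
  boosters <- numeric(0)
  if (!is.null(boosterPath)) {
    b <- utils::read.delim(boosterPath, header = FALSE,
                           stringsAsFactors = FALSE)
    boosters <- stats::setNames(as.numeric(b[[2]]), tolower(b[[1]]))
  }
  negators <- character(0)
  if (!is.null(negatorPath))
    negators <- tolower(readLines(negatorPath, warn = FALSE))
  methods::new("SentimentLexicon", valence = valence, boosters = boosters,
               negators = negators)
}

#' @rdname readLexicon
#' @details \code{syntheticLexicon()} loads the bundled synthetic lexicon
#'   with its boosters and negators.
#' @export
syntheticLexicon <- function() {
  readLexicon(
    system.file("extdata", "synthetic_lexicon.tsv", package = "infodemiR"),
    system.file("extdata", "synthetic_boosters.tsv", package = "infodemiR"),
    system.file("extdata", "synthetic_negators.txt", package = "infodemiR"))
}

# light word tokenisation that keeps case information alongside
.rawTokens <- function(text) {
  x <- gsub("(https?://\\S+|www\\.\\S+)", " ", text, ignore.case = TRUE)
  x <- gsub("'", "", x)
  toks <- strsplit(gsub("[^A-Za-z0-9 ]", " ", x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Prior sentiment scores for raw texts
#'
#' A documented subset of the classic lexicon-rule scorer: per-token valence
#' lookup; negation within a 3-token left window flips and damps the
#' valence (factor -0.74); a booster immediately in the window scales it;
#' an ALL-CAPS matched token (in mixed-case text) gains 0.733 emphasis;
#' exclamation marks amplify matched mass by 0.292 each (capped at 4).
#' Matched positive/negative weight and unmatched-token count form the
#' (positive, negative, neutral) masses, renormalised to the simplex. A
#' text with no lexicon hit scores (0, 0, 1).
#'
#' Any other scorer with the same signature and simplex output can be
#' plugged into the informed classifier in its place.
#'
#' @param texts character vector of raw texts.
#' @param lex a \code{\link{SentimentLexicon}}.
#' @return numeric matrix n x 3 with columns positive, negative, neutral;
#'   rows sum to 1.
#' @examples
#' lex <- syntheticLexicon()
#' priorScores(c("great news", "not great news", "meeting at noon"), lex)
#' @export
priorScores <- function(texts, lex) {
  stopifnot(methods::is(lex, "SentimentLexicon"))
  out <- t(vapply(texts, .priorScoresOne, numeric(3), lex = lex,
                  USE.NAMES = FALSE))
  colnames(out) <- c("positive", "negative", "neutral")
  out
}

.priorScoresOne <- function(text, lex) {
  if (is.na(text) || !nzchar(text)) return(c(0, 0, 1))
  toksRaw <- .rawTokens(text)
  if (!length(toksRaw)) return(c(0, 0, 1))
  toks <- tolower(toksRaw)
  allCapsText <- all(toksRaw == toupper(toksRaw))   # shouting text: no extra
  nExcl <- min(lengths(regmatches(text, gregexpr("!", text, fixed = TRUE))), 4)
  pos <- 0; neg <- 0; neu <- 0
  for (i in seq_along(toks)) {
    v <- lex@valence[toks[i]]
    if (is.na(v)) {
      # booster and negator tokens serve the rules; they carry no
      # sentiment mass of their own, in either direction
      if (!(toks[i] %in% lex@negators) &&
          !(toks[i] %in% names(lex@boosters))) neu <- neu + 1
      next
    }
    # ALL-CAPS emphasis only meaningful when the text itself is mixed case
    if (!allCapsText && toksRaw[i] == toupper(toksRaw[i]) &&
        grepl("[A-Z]", toksRaw[i]))
      v <- v + sign(v) * 0.733
    lo <- max(1, i - 3)
    if (i > 1) {
      win <- toks[lo:(i - 1)]
      bf <- lex@boosters[win]
      bf <- bf[!is.na(bf)]
      if (length(bf)) v <- v * prod(bf)
      if (any(win %in% lex@negators)) v <- v * -0.74
    }
    if (v > 0) pos <- pos + v else neg <- neg - v
  }
  amp <- 1 + 0.292 * nExcl
  pos <- pos * amp; neg <- neg * amp
  tot <- pos + neg + neu
  if (tot <= 0) return(c(0, 0, 1))
  c(pos, neg, neu) / tot
}
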