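## Reading tweet-like records, text normalisation, vocabulary construction
## and bag-of-words vectorisation.

#' Collection keywords excluded from vocabularies by default
#'
#' The query keywords used to collect an outbreak corpus dominate every
#' document; leaving them in the vocabulary would make all topics share the
#' same top words. They are therefore excluded by default when building a
#' vocabulary.
#' @return character vector of keywords.
#' @export
covidKeywords <- function() {
  c("coronavirus", "covid19", "covid-19", "covid_19",
    "coronovirusoutbreak", "covid2019", "covid", "coronaoutbreak")
}

#' Bundled English stopword list
#'
#' A standard snowball-style English stopword list, extended with "rt" (the
#' retweet marker) and apostrophe-stripped contraction forms ("dont",
#' "cant", ...), matching how punctuation stripping rewrites contractions.
#' @return character vector of stopwords.
#' @export
defaultStopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "infodemiR")
  readLines(path, warn = FALSE)
}

#' Preprocessing configuration
#'
#' @param stopwords character vector of stopwords to drop.
#' @param stem logical, apply the Porter stemmer.
#' @param urlToken token substituted for every URL before tokenisation.
#' @param keepHashtagWords keep the word of a hashtag (minus '#') as a token.
#' @param collapseRepeats collapse runs of >= 3 identical characters to 2.
#' @return a list of class \code{preprocConfig}.
#' @export
preprocConfig <- function(stopwords = defaultStopwords(), stem = TRUE,
                          urlToken = "xurl", keepHashtagWords = TRUE,
                          collapseRepeats = TRUE) {
  structure(list(stopwords = stopwords, stem = stem, urlToken = urlToken,
                 keepHashtagWords = keepHashtagWords,
                 collapseRepeats = collapseRepeats),
            class = "preprocConfig")
}

#' Normalise raw tweet text into a token list
#'
#' Pipeline: URLs are replaced by a literal placeholder token ("xurl")
#' before any punctuation stripping; text is lowercased; @-mentions are
#' removed; runs of three or more identical characters are collapsed to
#' two; apostrophes are deleted and all remaining punctuation and
#' non-printing characters become separators; stopwords are removed; the
#' survivors are Porter-stemmed. Token order is preserved. The function is
#' idempotent on its own output.
#'
#' @param raw character vector of raw texts.
#' @param cfg a \code{\link{preprocConfig}}.
#' @return a list of character token vectors, one per input text.
#' @examples
#' preprocessText("Stay HOME!!! https://t.co/x")[[1]]
#' @export
preprocessText <- function(raw, cfg = preprocConfig()) {
  stopifnot(is.character(raw))
  stopset <- cfg$stopwords
  out <- lapply(raw, function(x) {
    if (is.na(x) || !nzchar(x)) return(character())
    # URL -> placeholder, before punctuation stripping so the token survives
    x <- gsub("(https?://\\S+|www\\.\\S+|\\bt\\.co/\\S+)",
              paste0(" ", cfg$urlToken, " "), x, ignore.case = TRUE)
    x <- tolower(x)
    x <- gsub("@\\w+", " ", x)                     # mentions
    if (!cfg$keepHashtagWords) x <- gsub("#\\w+", " ", x)
    if (cfg$collapseRepeats) x <- gsub("(.)\\1{2,}", "\\1\\1", x)
    x <- gsub("'", "", x)                          # don't -> dont
    x <- gsub("[^a-z0-9 ]", " ", x)                # punctuation, controls
    toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    toks <- toks[!(toks %in% stopset)]
    if (cfg$stem) toks <- porterStem(toks)
    # stemming can surface a stopword stem only for non-words; drop again
    toks[!(toks %in% stopset)]
  })
  out
}

#' Read tweet-like records from CSV or JSON-lines
#'
#' @param path file path.
#' @param format "csv" or "jsonl".
#' @param fieldMap named character vector mapping canonical field names
#'   (\code{id}, \code{text}, \code{timestamp}, \code{location},
#'   \code{label}) to the file's column/key names. \code{label} and
#'   \code{location} are optional.
#' @param tz timezone for timestamp parsing (default UTC).
#' @return a data.frame with columns id, text, timestamp (POSIXct),
#'   location, label; rows with unparseable timestamps are dropped and
#'   counted in \code{attr(, "loadReport")$skipped}.
#' @export
readTweets <- function(path, format = c("jsonl", "csv"),
                       fieldMap = c(id = "id", text = "text",
                                    timestamp = "timestamp",
                                    location = "location", label = "label"),
                       tz = "UTC") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      raw <- data.frame()
    } else {
      recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
      keys <- unique(unlist(lapply(recs, names)))
      raw <- as.data.frame(
        lapply(stats::setNames(keys, keys), function(k)
          vapply(recs, function(r) {
            v <- r[[k]]
            if (is.null(v)) NA_character_ else as.character(v)
          }, character(1))),
        stringsAsFactors = FALSE)
    }
  }
  need <- c("id", "text", "timestamp")
  if (nrow(raw) == 0) {
    out <- data.frame(id = character(), text = character(),
                      timestamp = as.POSIXct(character(), tz = tz),
                      location = character(), label = character(),
                      stringsAsFactors = FALSE)
    attr(out, "loadReport") <- list(read = 0L, kept = 0L, skipped = 0L)
    return(out)
  }
  mapped <- function(f)
    if (f %in% names(fieldMap)) fieldMap[[f]] else NULL
  for (f in need) {
    col <- mapped(f)
    if (is.null(col) || !(col %in% names(raw)))
      stop("mapped column missing from input: ", f, " -> ",
           if (is.null(col)) "<unmapped>" else col)
  }
  getcol <- function(f) {
    col <- mapped(f)
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else
      rep(NA_character_, nrow(raw))
  }
  ts <- .parseTimestamp(getcol("timestamp"), tz = tz)
  ok <- !is.na(ts)
  out <- data.frame(id = getcol("id")[ok], text = getcol("text")[ok],
                    timestamp = ts[ok], location = getcol("location")[ok],
                    label = getcol("label")[ok], stringsAsFactors = FALSE)
  attr(out, "loadReport") <- list(read = nrow(raw), kept = sum(ok),
                                  skipped = sum(!ok))
  out
}

# several timestamp dialects, tried in order
.parseTimestamp <- function(x, tz = "UTC") {
  x <- as.character(x)
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
            "%d/%m/%Y %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = tz)
  for (f in fmts) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], format = f, tz = tz)
  }
  out
}

#' Write tweet-like records to CSV or JSON-lines
#'
#' Round-trips with \code{\link{readTweets}} under the default field map.
#' @param records data.frame as returned by \code{readTweets}.
#' @param path output file path.
#' @param format "csv" or "jsonl".
#' @export
writeTweets <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  df <- data.frame(id = records$id, text = records$text,
                   timestamp = format(records$timestamp,
                                      "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                   location = records$location, label = records$label,
                   stringsAsFactors = FALSE)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      rec <- as.list(df[i, , drop = FALSE])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Build a frequency-filtered vocabulary
#'
#' Keeps exactly the terms whose total corpus frequency is at least
#' \code{minCount} and that are not excluded, ordered by descending
#' frequency, ties broken lexicographically.
#'
#' @param docs list of token vectors (output of \code{preprocessText}).
#' @param minCount minimum corpus frequency (default 5; removes rare words
#'   at tweet-corpus scale).
#' @param exclude terms never admitted (default the collection keywords).
#' @return character vector of terms with a \code{frequency} attribute.
#' @export
buildVocabulary <- function(docs, minCount = 5,
                            exclude = covidKeywords()) {
  stopifnot(minCount >= 1)
  toks <- unlist(docs, use.names = FALSE)
  if (!length(toks)) {
    out <- character()
    attr(out, "frequency") <- integer()
    return(out)
  }
  tab <- table(toks)
  tab <- tab[!(names(tab) %in% exclude)]
  tab <- tab[tab >= minCount]
  ord <- order(-as.integer(tab), names(tab))
  out <- names(tab)[ord]
  attr(out, "frequency") <- as.integer(tab)[ord]
  out
}

#' Vectorise token lists into a BowCorpus
#'
#' Entry (i, j) is the count of vocabulary term j in document i;
#' out-of-vocabulary tokens are ignored.
#'
#' @param docs list of token vectors.
#' @param vocab character vector of vocabulary terms.
#' @param ids document ids (default doc1..docN).
#' @return a \code{\link{BowCorpus}}.
#' @export
bowCorpus <- function(docs, vocab, ids = NULL) {
  n <- length(docs)
  if (is.null(ids)) ids <- paste0("doc", seq_len(n))
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  vocab <- as.character(vocab)
  ii <- integer(); jj <- integer(); xx <- integer()
  for (i in seq_len(n)) {
    idx <- match(docs[[i]], vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      t <- table(idx)
      ii <- c(ii, rep.int(i, length(t)))
      jj <- c(jj, as.integer(names(t)))
      xx <- c(xx, as.integer(t))
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n, length(vocab)),
                            dimnames = list(ids, vocab))
  methods::new("BowCorpus", counts = m)
}

#' Read a field map from a key=value config file
#'
#' One \code{canonical=column} pair per line (blank lines and lines
#' starting with \code{#} ignored), e.g. \code{text=tweet_body}. Keys are
#' the canonical record fields (id, text, timestamp, location, label).
#'
#' @param path config file path.
#' @return named character vector usable as \code{fieldMap} in
#'   \code{\link{readTweets}}.
#' @export
readFieldMap <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed field-map line: ", lines[bad][1])
  stats::setNames(trimws(vapply(kv, `[[`, "", 2)),
                  trimws(vapply(kv, `[[`, "", 1)))
}

#' Read a gazetteer and map free-text locations to canonical codes
#'
#' The gazetteer is a two-column CSV (pattern, code). Matching is
#' case-insensitive exact match on the trimmed location string; unmatched
#' non-empty locations map to "oth", empty/missing to "oth" as well.
#'
#' @param path gazetteer CSV; default the bundled Australian gazetteer
#'   (capital cities, states/territories, country).
#' @return a named character vector pattern -> code.
#' @export
readGazetteer <- function(path = system.file("extdata", "gazetteer_au.csv",
                                             package = "infodemiR")) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  stats::setNames(g$code, tolower(trimws(g$pattern)))
}

#' @rdname readGazetteer
#' @param location character vector of free-text location labels.
#' @param gazetteer named vector pattern -> code.
#' @export
mapLocation <- function(location, gazetteer = readGazetteer()) {
  key <- tolower(trimws(as.character(location)))
  out <- unname(gazetteer[key])
  out[is.na(out) | !nzchar(key) | is.na(key)] <- "oth"
  out
}
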