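## Slicing a tweet stream by calendar time (ISO weeks starting Monday, or
## days; half-open intervals) and location, and the per-slice analyses:
## volume, positive-sentiment ratio, topic evolution, SBS series.

.periodStart <- function(ts, granularity) {
  d <- as.Date(format(ts, "%Y-%m-%d", tz = "UTC"))
  if (granularity == "day") return(d)
  # ISO week: Monday start; %u gives 1 (Mon) .. 7 (Sun)
  d - (as.integer(format(d, "%u")) - 1L)
}

#' Assign records to disjoint time (x location) slices
#'
#' Periods are half-open calendar intervals: a record exactly on a week
#' boundary belongs to the week it opens. Every record lands in exactly one
#' slice.
#'
#' @param records data.frame with columns id, timestamp (POSIXct) and
#'   optionally location.
#' @param granularity "week" (ISO weeks, Monday start) or "day".
#' @param byLocation also split by the location column.
#' @return data.frame with columns id, period (Date, slice start) and
#'   location ("all" when not splitting); attribute \code{granularity}.
#' @export
discretize <- function(records, granularity = c("week", "day"),
                       byLocation = FALSE) {
  granularity <- match.arg(granularity)
  if (!nrow(records)) {
    out <- data.frame(id = character(), period = as.Date(character()),
                      location = character())
    attr(out, "granularity") <- granularity
    return(out)
  }
  stopifnot(!anyNA(records$timestamp))
  out <- data.frame(
    id = records$id,
    period = .periodStart(records$timestamp, granularity),
    location = if (byLocation) as.character(records$location) else "all",
    stringsAsFactors = FALSE)
  attr(out, "granularity") <- granularity
  out
}

# full period range covered by a slicing (so empty slices can be reported)
.periodSeq <- function(slices) {
  if (!nrow(slices)) return(as.Date(character()))
  by <- if (attr(slices, "granularity") == "week") 7L else 1L
  seq(min(slices$period), max(slices$period), by = by)
}

#' Per-slice record counts
#'
#' Counts sum to the total number of records (the slices partition the
#' stream); periods inside the covered range with no records are reported
#' with count 0.
#'
#' @param slices output of \code{\link{discretize}}.
#' @return data.frame with columns period, location, n.
#' @export
volumeTable <- function(slices) {
  periods <- .periodSeq(slices)
  locs <- if (nrow(slices)) sort(unique(slices$location)) else character()
  grid <- expand.grid(period = periods, location = locs,
                      stringsAsFactors = FALSE)
  if (!nrow(grid)) return(data.frame(period = as.Date(character()),
                                     location = character(), n = integer()))
  key <- paste(slices$period, slices$location)
  tab <- table(key)
  grid$n <- as.integer(tab[paste(grid$period, grid$location)])
  grid$n[is.na(grid$n)] <- 0L
  grid[order(grid$period, grid$location), , drop = FALSE]
}

#' Per-slice positive-sentiment ratio
#'
#' Ratio of records whose predicted class equals \code{positive} to the
#' slice total; a period-location cell with no records gets NA (undefined,
#' not zero).
#'
#' @param records the tweet data.frame (id, text, ...).
#' @param slices output of \code{\link{discretize}} for those records.
#' @param model a trained \code{\link{SentimentModel}}.
#' @param vocab vocabulary used when the model was trained (token ids).
#' @param lex \code{\link{SentimentLexicon}} for the prior channel.
#' @param positive name of the positive class.
#' @param cfg optional \code{\link{preprocConfig}}.
#' @return data.frame period, location, n, nPositive, ratio.
#' @export
sentimentRatio <- function(records, slices, model, vocab, lex,
                           positive = "pos", cfg = preprocConfig()) {
  vol <- volumeTable(slices)
  if (!nrow(records)) {
    vol$nPositive <- integer(0); vol$ratio <- numeric(0)
    return(vol)
  }
  docs <- preprocessText(records$text, cfg)
  idsL <- .tokensToIds(docs, vocab, model@config$maxLen)
  pr <- priorScores(records$text, lex)
  pred <- predictSentiment(model, idsL, pr)$labels
  isPos <- pred == positive
  key <- paste(slices$period, slices$location)
  posTab <- tapply(isPos[match(slices$id, records$id)], key, sum)
  vol$nPositive <- as.integer(posTab[paste(vol$period, vol$location)])
  vol$nPositive[is.na(vol$nPositive) & vol$n > 0] <- 0L
  vol$ratio <- ifelse(vol$n > 0, vol$nPositive / vol$n, NA_real_)
  vol
}

#' Per-slice topic prevalence and top-term frequencies
#'
#' For each non-empty slice: the mean topic-proportion vector (on the
#' simplex) under one fitted model, and, per topic, the model's global
#' top-n words re-ranked by their frequency inside the slice. Topic
#' evolution is thus approximated by per-slice inference with a single
#' fitted model. Slices with no documents are skipped and reported.
#'
#' @param model a fitted \code{\link{TopicModel}}.
#' @param bow the \code{\link{BowCorpus}} (documents = records).
#' @param slices output of \code{\link{discretize}}; ids must match the
#'   corpus document ids.
#' @param ctx optional contextual embeddings for the corpus.
#' @param n top-word depth (default 10).
#' @return list with \code{meanTheta} (data.frame period, location,
#'   topic1..T), \code{topTerms} (nested list slice -> topic -> ranked
#'   terms) and \code{report}.
#' @export
topicEvolution <- function(model, bow, slices, ctx = NULL, n = 10) {
  theta <- inferTheta(model, bow, ctx)
  m <- counts(bow)
  Tn <- nTopics(model)
  globalTop <- lapply(seq_len(Tn), function(j) topWords(model, j, n))
  key <- paste(slices$period, slices$location)
  keys <- unique(key[order(slices$period, slices$location)])
  rowsOut <- list(); topOut <- list(); skipped <- character(0)
  for (k in keys) {
    idsK <- slices$id[key == k]
    idx <- match(idsK, rownames(theta))
    idx <- idx[!is.na(idx)]
    if (!length(idx)) { skipped <- c(skipped, k); next }
    mt <- colMeans(theta[idx, , drop = FALSE])
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    rowsOut[[k]] <- data.frame(period = as.Date(parts[1]),
                               location = parts[2],
                               t(mt), stringsAsFactors = FALSE)
    sliceCounts <- Matrix::colSums(m[idx, , drop = FALSE])
    topOut[[k]] <- lapply(globalTop, function(tw) {
      f <- sliceCounts[tw]
      f[is.na(f)] <- 0
      tw[order(-f, tw)]
    })
  }
  meanTheta <- do.call(rbind, rowsOut)
  if (!is.null(meanTheta)) {
    names(meanTheta)[-(1:2)] <- paste0("topic", seq_len(Tn))
    rownames(meanTheta) <- NULL
  }
  list(meanTheta = meanTheta, topTerms = topOut,
       report = list(skippedSlices = skipped))
}

#' Per-slice Semantic Brand Score series
#'
#' Builds a co-occurrence network per non-empty slice and computes the SBS
#' of the query concepts in it; a concept absent from a slice scores the
#' standardised minimum for that slice (raw components all 0).
#'
#' @param docs list of token vectors, named by document id.
#' @param slices output of \code{\link{discretize}}.
#' @param concepts character vector of concepts to trace.
#' @param minEdgeWeight edge filter per slice network.
#' @return data.frame with columns period, location, concept, prev, div,
#'   con, z_prev, z_div, z_con, sbs.
#' @export
sbsOverTime <- function(docs, slices, concepts, minEdgeWeight = 1) {
  stopifnot(!is.null(names(docs)))
  key <- paste(slices$period, slices$location)
  keys <- unique(key[order(slices$period, slices$location)])
  out <- list()
  for (k in keys) {
    idsK <- slices$id[key == k]
    dk <- docs[names(docs) %in% idsK]
    if (!length(dk)) next
    net <- buildCooccurrence(dk, minEdgeWeight = minEdgeWeight)
    res <- suppressWarnings(sbs(dk, net, concepts))
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    res <- cbind(period = as.Date(parts[1]), location = parts[2], res)
    out[[k]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
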