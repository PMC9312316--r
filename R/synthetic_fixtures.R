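## Deterministic corpus generators. Each is a pure function of its
## arguments: the seed is applied at entry to R's RNG, so identical calls
## give identical output. The generators emulate the statistical structure
## the methods assume (sparse planted topics, imperfectly lexicon-aligned
## sentiment labels, an epidemic-shaped weekly volume curve); they do not
## emulate real tweet metadata beyond the fields the pipeline reads.

#' Planted-topic corpus generator
#'
#' Documents are drawn token-by-token from a mixture of sparse topic-word
#' distributions: each topic owns a disjoint block of anchor words holding
#' \code{anchorMass} of its probability (Zipf-weighted within the block),
#' with the rest spread uniformly over the shared tail of the vocabulary.
#' Document-topic proportions are Dirichlet(\code{alpha}); a fraction of
#' documents carries its argmax topic as a label.
#'
#' @param seed integer seed.
#' @param nDocs number of documents.
#' @param nTopics number of planted topics T (>= 2).
#' @param vocabSize vocabulary size V (>= 10 * T for disjoint sparsity).
#' @param docLengthMean mean document length (Poisson, floored at 3).
#' @param anchorMass probability mass a topic puts on its anchor block.
#' @param alpha Dirichlet concentration of document-topic proportions.
#' @param labelFraction fraction of documents receiving a label.
#' @param includeEmptyDoc append one empty document (degenerate toggle for
#'   error-path testing).
#' @return list with \code{bow} (BowCorpus), \code{docs} (token lists),
#'   \code{beta} (T x V ground truth), \code{theta} (n x T ground truth),
#'   \code{labels} (named character vector for the labelled subset),
#'   \code{tokenTopicCounts} (T x V realised token draws per topic).
#' @export
generateTopicCorpus <- function(seed = 1L, nDocs = 2000, nTopics = 5,
                                vocabSize = 200, docLengthMean = 20,
                                anchorMass = 0.85, alpha = 0.2,
                                labelFraction = 0.3,
                                includeEmptyDoc = FALSE) {
  stopifnot(nTopics >= 2)
  if (vocabSize < 10 * nTopics)
    stop("infeasible sparsity: need vocabSize >= 10 * nTopics")
  set.seed(seed)
  V <- vocabSize; Tn <- nTopics
  vocab <- sprintf("w%03d", seq_len(V))
  anchorSize <- floor(V / (2 * Tn))
  beta <- matrix(0, Tn, V, dimnames = list(NULL, vocab))
  tailIdx <- (Tn * anchorSize + 1):V
  for (j in seq_len(Tn)) {
    anchors <- ((j - 1) * anchorSize + 1):(j * anchorSize)
    zipf <- 1 / seq_len(anchorSize)
    beta[j, anchors] <- anchorMass * zipf / sum(zipf)
    beta[j, tailIdx] <- (1 - anchorMass) / length(tailIdx)
  }
  theta <- matrix(stats::rgamma(nDocs * Tn, alpha), nDocs, Tn)
  theta <- theta / rowSums(theta)
  lens <- pmax(stats::rpois(nDocs, docLengthMean), 3L)
  docs <- vector("list", nDocs)
  tokenTopicCounts <- matrix(0L, Tn, V, dimnames = list(NULL, vocab))
  for (i in seq_len(nDocs)) {
    zt <- sample.int(Tn, lens[i], replace = TRUE, prob = theta[i, ])
    wt <- vapply(zt, function(j)
      sample.int(V, 1, prob = beta[j, ]), integer(1))
    for (k in seq_along(zt))
      tokenTopicCounts[zt[k], wt[k]] <- tokenTopicCounts[zt[k], wt[k]] + 1L
    docs[[i]] <- vocab[wt]
  }
  ids <- sprintf("doc%05d", seq_len(nDocs))
  names(docs) <- ids
  rownames(theta) <- ids
  gt <- apply(theta, 1, which.max)
  nLab <- round(labelFraction * nDocs)
  labIdx <- sort(sample.int(nDocs, nLab))
  labels <- stats::setNames(paste0("t", gt[labIdx]), ids[labIdx])
  if (includeEmptyDoc) {
    docs <- c(docs, list(docEMPTY = character()))
    ids <- c(ids, "docEMPTY")
  }
  bow <- bowCorpus(docs, vocab, ids = names(docs))
  list(bow = bow, docs = docs, beta = beta, theta = theta,
       labels = labels, tokenTopicCounts = tokenTopicCounts)
}

#' Sentiment-labelled corpus generator
#'
#' Each document plants one to three lexicon terms of one sentiment sign
#' amid neutral filler words; its label agrees with that sign with
#' probability \code{alignment} (the labels correlate imperfectly with the
#' lexicon, as real annotation does).
#'
#' @param seed integer seed.
#' @param n number of documents.
#' @param lex a \code{\link{SentimentLexicon}} supplying the planted terms.
#' @param alignment probability that the label equals the planted sign.
#' @param neutralVocabSize number of distinct neutral filler words.
#' @param lengthRange range of document lengths (filler + planted terms).
#' @param startDate first timestamp date.
#' @param days time window over which timestamps spread uniformly.
#' @param singleClass force all labels to "pos" (degenerate toggle).
#' @return data.frame: id, text, timestamp, location, label ("pos"/"neg"),
#'   plus a \code{plantedSign} column with the planted lexicon sign.
#' @export
generateSentimentCorpus <- function(seed = 1L, n = 1000,
                                    lex = syntheticLexicon(),
                                    alignment = 0.8,
                                    neutralVocabSize = 60,
                                    lengthRange = 6:14,
                                    startDate = "2020-01-01", days = 60,
                                    singleClass = FALSE) {
  set.seed(seed)
  posTerms <- names(lex@valence)[lex@valence > 0]
  negTerms <- names(lex@valence)[lex@valence < 0]
  neutral <- sprintf("nw%02d", seq_len(neutralVocabSize))
  sign <- sample(c("pos", "neg"), n, replace = TRUE)
  lens <- sample(lengthRange, n, replace = TRUE)
  text <- character(n)
  for (i in seq_len(n)) {
    k <- sample(1:3, 1)
    planted <- sample(if (sign[i] == "pos") posTerms else negTerms, k,
                      replace = TRUE)
    filler <- sample(neutral, max(lens[i] - k, 2), replace = TRUE)
    words <- sample(c(planted, filler))
    text[i] <- paste(words, collapse = " ")
  }
  agree <- stats::runif(n) < alignment
  label <- ifelse(agree, sign, ifelse(sign == "pos", "neg", "pos"))
  if (singleClass) label <- rep("pos", n)
  t0 <- as.POSIXct(paste(startDate, "00:00:00"), tz = "UTC")
  ts <- t0 + stats::runif(n, 0, days * 86400)
  data.frame(id = sprintf("s%06d", seq_len(n)), text = text,
             timestamp = ts,
             location = sample(c("sydney", "melbourne", "brisbane",
                                 "australia"), n, replace = TRUE),
             label = label, plantedSign = sign,
             stringsAsFactors = FALSE)
}

.defaultLocationProbs <- function() {
  c(sydney = 0.20, melbourne = 0.18, nsw = 0.10, victoria = 0.09,
    queensland = 0.08, brisbane = 0.07, perth = 0.06, wa = 0.04,
    adelaide = 0.04, sa = 0.02, act = 0.03, canberra = 0.02,
    tasmania = 0.01, hobart = 0.01, nt = 0.01, darwin = 0.01,
    australia = 0.02, "somewhere else" = 0.01)
}

#' Epidemic-shaped spatio-temporal tweet stream generator
#'
#' Weekly volumes follow a logistic rise to a plateau followed by an
#' exponential decay (the shape of an outbreak conversation: quiet weeks,
#' a burst, a peak, a slow fall); locations are drawn from a fixed
#' categorical distribution over city/state/country labels. Texts mix two
#' topical word pools whose ratio shifts linearly across the window (an
#' early theme giving way to a late one) plus sentiment-bearing lexicon
#' terms, so every downstream analysis has signal to find.
#'
#' @param seed integer seed.
#' @param nTotal total number of records.
#' @param startDate first Monday of the window.
#' @param weeks number of weekly periods.
#' @param riseRate,riseMid logistic rise parameters (per-week).
#' @param decayStart,decayRate exponential decay start week and rate.
#' @param locationProbs named probability vector over location labels.
#' @param lex lexicon supplying sentiment terms for the texts.
#' @return data.frame: id, text, timestamp, location, label (NA).
#' @export
generateTweetStream <- function(seed = 1L, nTotal = 2000,
                                startDate = "2019-11-25", weeks = 19,
                                riseRate = 0.8, riseMid = 12,
                                decayStart = 17, decayRate = 0.35,
                                locationProbs = .defaultLocationProbs(),
                                lex = syntheticLexicon()) {
  set.seed(seed)
  wk <- seq_len(weeks)
  wgt <- 1 / (1 + exp(-riseRate * (wk - riseMid))) *
    exp(-decayRate * pmax(0, wk - decayStart)) + 0.002
  wgt <- wgt / sum(wgt)
  counts <- as.integer(stats::rmultinom(1, nTotal, wgt))
  earlyPool <- c("china", "wuhan", "travel", "ban", "island", "outbreak",
                 "flight", "border")
  latePool <- c("lockdown", "home", "work", "cases", "testing", "masks",
                "distancing", "toilet", "paper", "hands", "wash")
  sentTerms <- names(lex@valence)
  t0 <- as.POSIXct(paste(startDate, "00:00:00"), tz = "UTC")
  rows <- list()
  idc <- 0L
  for (w in wk) {
    nw <- counts[w]
    if (!nw) next
    earlyP <- 0.8 - 0.6 * (w - 1) / max(weeks - 1, 1)
    for (i in seq_len(nw)) {
      idc <- idc + 1L
      len <- sample(5:12, 1)
      nEarly <- stats::rbinom(1, len, earlyP)
      words <- c(sample(earlyPool, nEarly, replace = TRUE),
                 sample(latePool, len - nEarly, replace = TRUE))
      if (stats::runif(1) < 0.7)
        words <- c(words, sample(sentTerms, 1))
      rows[[idc]] <- data.frame(
        id = sprintf("tw%06d", idc),
        text = paste(sample(words), collapse = " "),
        timestamp = t0 + (w - 1) * 7 * 86400 +
          stats::runif(1, 0, 7 * 86400 - 1),
        location = sample(names(locationProbs), 1, prob = locationProbs),
        label = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
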