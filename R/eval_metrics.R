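## Topic-quality metrics (NPMI coherence, embedding coherence, inverted
## rank-biased overlap) and the six classification metrics.

#' NPMI topic coherence
#'
#' For each topic, the mean over unordered top-word pairs of
#' log(P(wi,wj) / (P(wi) P(wj))) / (-log P(wi,wj)), with document-level
#' co-occurrence probabilities and epsilon smoothing inside both
#' logarithms; the score is averaged over topics. Values lie in [-1, 1]:
#' 1 for words that always co-occur, -1 (in the epsilon -> 0 limit) for
#' words that never do. Words absent from the corpus are handled by the
#' smoothing and flagged in \code{attr(, "report")}.
#'
#' @param topics list of ranked top-word character vectors.
#' @param bow a \code{\link{BowCorpus}} giving the reference counts.
#' @param epsilon smoothing constant (default 1e-12).
#' @return scalar mean NPMI with a per-topic attribute \code{byTopic}.
#' @export
npmi <- function(topics, bow, epsilon = 1e-12) {
  m <- counts(bow)
  stopifnot(nrow(m) > 0)
  words <- unique(unlist(topics))
  present <- words[words %in% colnames(m)]
  missing <- setdiff(words, present)
  N <- nrow(m)
  sub <- m[, present, drop = FALSE]
  bin <- sub
  bin@x <- rep(1, length(bin@x))
  df <- Matrix::colSums(bin)
  joint <- as.matrix(Matrix::crossprod(bin))
  pw <- stats::setNames(as.numeric(df) / N, present)
  byTopic <- vapply(topics, function(tw) {
    tw <- unique(tw)
    if (length(tw) < 2) return(NA_real_)
    vals <- c()
    for (a in seq_len(length(tw) - 1)) for (b in (a + 1):length(tw)) {
      wi <- tw[a]; wj <- tw[b]
      pi <- if (wi %in% present) pw[[wi]] else epsilon
      pj <- if (wj %in% present) pw[[wj]] else epsilon
      pij <- if (wi %in% present && wj %in% present)
        joint[wi, wj] / N else 0
      num <- log(pij + epsilon) - log(pi * pj)
      den <- -log(pij + epsilon)
      vals <- c(vals, num / den)
    }
    mean(vals)
  }, numeric(1))
  out <- mean(byTopic, na.rm = TRUE)
  attr(out, "byTopic") <- byTopic
  attr(out, "report") <- list(missingWords = missing)
  out
}

#' Embedding-based topic coherence
#'
#' Mean over topics of the mean pairwise cosine similarity of the top
#' words' embedding vectors. Words without an embedding are dropped (and
#' reported); a topic left with fewer than two embedded words is skipped
#' and reported.
#'
#' @param topics list of ranked top-word character vectors.
#' @param embeddings numeric matrix with one row per word (rownames are the
#'   words), e.g. from \code{\link{readWordVectors}}.
#' @return scalar mean coherence with \code{byTopic} and \code{report}
#'   attributes.
#' @export
ewetc <- function(topics, embeddings) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  missing <- character(0)
  skipped <- integer(0)
  byTopic <- rep(NA_real_, length(topics))
  for (k in seq_along(topics)) {
    tw <- unique(topics[[k]])
    have <- tw[tw %in% rownames(embeddings)]
    missing <- union(missing, setdiff(tw, have))
    if (length(have) < 2) { skipped <- c(skipped, k); next }
    E <- embeddings[have, , drop = FALSE]
    nrm <- sqrt(rowSums(E^2))
    E <- E / pmax(nrm, 1e-12)
    S <- E %*% t(E)
    byTopic[k] <- mean(S[upper.tri(S)])
  }
  out <- mean(byTopic, na.rm = TRUE)
  attr(out, "byTopic") <- byTopic
  attr(out, "report") <- list(missingWords = missing,
                              skippedTopics = skipped)
  out
}

#' Rank-biased overlap of two ranked lists
#'
#' Finite-list RBO with the standard extrapolated tail: agreement observed
#' to the evaluation depth is carried forward with persistence p. Identical
#' lists score 1, fully disjoint lists 0.
#'
#' @param a,b character vectors (ranked lists, no duplicates).
#' @param p persistence parameter in (0, 1); 0.9 is the literature's
#'   standard for top-10 lists.
#' @return scalar in [0, 1].
#' @export
rbo <- function(a, b, p = 0.9) {
  if (!length(a) || !length(b)) stop("empty ranked list")
  stopifnot(p > 0, p < 1, !anyDuplicated(a), !anyDuplicated(b))
  s <- min(length(a), length(b))
  l <- max(length(a), length(b))
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  X <- numeric(l)  # overlap at each depth (short list capped at s)
  for (d in seq_len(l))
    X[d] <- length(intersect(a[seq_len(min(d, s))], b[seq_len(d)]))
  sum1 <- sum(X / seq_len(l) * p^seq_len(l))
  sum2 <- 0
  if (l > s) {
    ds <- (s + 1):l
    sum2 <- sum(X[s] * (ds - s) / (s * ds) * p^ds)
  }
  ext <- ((X[l] - X[s]) / l + X[s] / s) * p^l
  (1 - p) / p * (sum1 + sum2) + ext
}

#' Inverted rank-biased overlap (topic diversity)
#'
#' 1 minus the mean pairwise RBO over all unordered topic pairs: 1 when all
#' topics' top-word lists are fully disjoint, 0 when all are identical.
#'
#' @param topics list of ranked top-word character vectors.
#' @param p persistence parameter passed to \code{\link{rbo}}.
#' @return scalar in [0, 1].
#' @export
irbo <- function(topics, p = 0.9) {
  Tn <- length(topics)
  if (Tn < 2) stop("need at least two topics")
  vals <- c()
  for (i in seq_len(Tn - 1)) for (j in (i + 1):Tn)
    vals <- c(vals, rbo(topics[[i]], topics[[j]], p))
  1 - mean(vals)
}

#' The six classification metrics
#'
#' Accuracy, precision, recall, F1 (for the declared positive class),
#' Cohen's kappa and AUC (rank statistic over the positive-class
#' probability; binary tasks only). Predicted labels are the row-wise
#' argmax of \code{probs}, ties toward the lower class index. If the labels
#' contain a single class the AUC is undefined and returned as NA with a
#' warning.
#'
#' @param labels true labels (character/factor).
#' @param probs numeric matrix n x K of class probabilities with class
#'   names as colnames, or a vector of positive-class probabilities.
#' @param positive the positive class (default: last class alphabetically
#'   among those present, so "pos" beats "neg").
#' @return named list with accuracy, precision, recall, f1, kappa, auc.
#' @export
classificationMetrics <- function(labels, probs, positive = NULL) {
  labels <- as.character(labels)
  if (is.matrix(probs)) {
    classes <- colnames(probs)
    if (is.null(classes)) classes <- sort(unique(labels))
    pred <- classes[apply(probs, 1, which.max)]
  } else {
    classes <- sort(unique(labels))
    stopifnot(length(classes) <= 2)
    if (is.null(positive)) positive <- classes[length(classes)]
    negClass <- setdiff(classes, positive)
    if (!length(negClass)) negClass <- paste0("not_", positive)
    pred <- ifelse(probs >= 0.5, positive, negClass[1])
    probs <- cbind(1 - probs, probs)
    colnames(probs) <- c(negClass[1], positive)
    classes <- c(negClass[1], positive)
  }
  if (is.null(positive)) positive <- classes[length(classes)]
  acc <- mean(pred == labels)
  tp <- sum(pred == positive & labels == positive)
  fp <- sum(pred == positive & labels != positive)
  fn <- sum(pred != positive & labels == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  # Cohen's kappa (multi-class)
  tabClasses <- union(classes, unique(labels))
  po <- acc
  pe <- sum(vapply(tabClasses, function(k)
    mean(pred == k) * mean(labels == k), numeric(1)))
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  # AUC via the Mann-Whitney rank statistic (ties get mean ranks)
  auc <- NA_real_
  if (length(unique(labels)) < 2) {
    warning("single-class labels: AUC undefined")
  } else if (length(setdiff(unique(labels), classes)) == 0 &&
             length(unique(labels)) == 2) {
    sc <- probs[, positive]
    isPos <- labels == positive
    r <- rank(sc)
    n1 <- sum(isPos); n0 <- sum(!isPos)
    auc <- (sum(r[isPos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(accuracy = acc, precision = precision, recall = recall, f1 = f1,
       kappa = kappa, auc = auc)
}

#' Read word embeddings in word2vec text format
#'
#' Plain-text format: an optional "n dim" header line, then one word per
#' line followed by its vector components.
#'
#' @param path file path.
#' @return numeric matrix with words as rownames.
#' @export
readWordVectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(matrix(numeric(0), 0, 0))
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first))))
    lines <- lines[-1]
  parts <- strsplit(trimws(lines), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1)
  vecs <- t(vapply(parts, function(x) as.numeric(x[-1]),
                   numeric(length(parts[[1]]) - 1)))
  rownames(vecs) <- words
  vecs
}

#' Deterministic contextual document embeddings from the corpus itself
#'
#' A truncated-SVD embedding of the (log-scaled) document-term matrix:
#' the default provider for the topic model's contextual-fusion path when
#' no pretrained sentence encoder is available. Any per-document embedding
#' table with row-aligned document ids can be used instead.
#'
#' @param bow a \code{\link{BowCorpus}}.
#' @param dim embedding width (clipped to the matrix rank).
#' @return numeric matrix n x dim with document ids as rownames.
#' @export
svdEmbeddings <- function(bow, dim = 20) {
  X <- as.matrix(counts(bow))
  X <- log1p(X)
  dim <- min(dim, nrow(X) - 1, ncol(X))
  sv <- svd(X, nu = dim, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(dim)], dim)
  rownames(emb) <- rownames(X)
  emb
}
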