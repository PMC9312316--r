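#' @import methods
#' @importFrom Matrix Matrix rowSums colSums crossprod t
#' @importFrom stats rnorm runif rpois sd setNames aggregate quantile
#' @importFrom utils head read.csv write.csv
NULL

#' BowCorpus: a bag-of-words document-term matrix with its vocabulary
#'
#' The central container for all count-based computation: a sparse
#' documents x terms nonnegative integer matrix whose column names are the
#' vocabulary (ordered by descending corpus frequency, ties lexicographic)
#' and whose row names are the document ids.
#'
#' @slot counts a \code{\link[Matrix]{dgCMatrix}} of nonnegative counts;
#'   rownames are document ids, colnames are vocabulary terms.
#' @export
setClass("BowCorpus", representation(counts = "Matrix"))

setValidity("BowCorpus", function(object) {
  m <- object@counts
  msg <- character()
  if (is.null(colnames(m)) && ncol(m) > 0)
    msg <- c(msg, "counts must have vocabulary terms as colnames")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "vocabulary terms must be unique")
  if (is.null(rownames(m)) && nrow(m) > 0)
    msg <- c(msg, "counts must have document ids as rownames")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "document ids must be unique")
  if (nrow(m) > 0 && ncol(m) > 0 && min(m) < 0)
    msg <- c(msg, "counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' SentimentLexicon: term valences plus booster and negator rules
#'
#' @slot valence named numeric vector, term -> signed valence.
#' @slot boosters named numeric vector, term -> multiplicative factor (> 0).
#' @slot negators character vector of negation terms.
#' @export
setClass("SentimentLexicon", representation(
  valence = "numeric", boosters = "numeric", negators = "character"))

setValidity("SentimentLexicon", function(object) {
  msg <- character()
  if (length(object@valence) && (is.null(names(object@valence)) ||
      any(!is.finite(object@valence))))
    msg <- c(msg, "valence must be a named finite numeric vector")
  if (length(object@boosters) && (is.null(names(object@boosters)) ||
      any(object@boosters <= 0)))
    msg <- c(msg, "boosters must be named and strictly positive")
  if (length(msg)) msg else TRUE
})

#' SentimentModel: a fitted informed neural network
#'
#' Holds all learned tensors of the informed sentiment classifier: the word
#' embedding table, the LSTM cell, the data head FCd, the knowledge head
#' FCk (absent when the prior branch is ablated) and the softmax output
#' layer FCs, together with the configuration and the per-epoch training
#' loss.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot config the \code{\link{innConfig}} list used to build the model.
#' @slot classes character vector of class labels (output order).
#' @slot trainingLog numeric vector, mean training loss per epoch.
#' @export
setClass("SentimentModel", representation(
  params = "list", config = "list", classes = "character",
  trainingLog = "numeric"))

setValidity("SentimentModel", function(object) {
  if (length(object@classes) < 2) "at least 2 classes required" else TRUE
})

#' TopicModel: a fitted semi-supervised neural topic model
#'
#' @slot params named list of all learned tensors: encoder layers, the
#'   contextual projection (when fusion is enabled), the T x V topic-word
#'   weight matrix \code{beta} and the classifier head.
#' @slot config the \code{\link{sntmConfig}} list used for fitting.
#' @slot vocabulary character vector of the V terms (beta column order).
#' @slot classes character vector of label classes ("" when unsupervised).
#' @slot trainingLog numeric vector, mean training loss per epoch.
#' @export
setClass("TopicModel", representation(
  params = "list", config = "list", vocabulary = "character",
  classes = "character", trainingLog = "numeric"))

setValidity("TopicModel", function(object) {
  b <- object@params$beta
  msg <- character()
  if (!is.null(b)) {
    if (!all(is.finite(b))) msg <- c(msg, "beta must be finite")
    if (ncol(b) != length(object@vocabulary))
      msg <- c(msg, "beta columns must match vocabulary length")
  }
  if (length(msg)) msg else TRUE
})

#' CooccurrenceNetwork: an undirected weighted term co-occurrence graph
#'
#' Nodes are vocabulary terms; an edge (u, v) with weight w means u and v
#' co-occur in w documents (w >= 1, no self loops).
#'
#' @slot nodes character vector of all node terms (isolated nodes allowed).
#' @slot edges data.frame with columns \code{u}, \code{v}, \code{weight};
#'   each unordered pair appears once with \code{u < v}.
#' @export
setClass("CooccurrenceNetwork", representation(
  nodes = "character", edges = "data.frame"))

setValidity("CooccurrenceNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("u", "v", "weight") %in% names(e)))
    msg <- c(msg, "edges needs columns u, v, weight")
  else if (nrow(e)) {
    if (any(e$u == e$v)) msg <- c(msg, "self loops are not allowed")
    if (any(e$weight < 1)) msg <- c(msg, "edge weights must be >= 1")
    if (any(e$u > e$v)) msg <- c(msg, "edges must be canonical (u < v)")
    if (anyDuplicated(paste(e$u, e$v)))
      msg <- c(msg, "duplicate edges not allowed")
    if (!all(c(e$u, e$v) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed in nodes")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "nodes must be unique")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------ generics

#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))
#' @export
setGeneric("vocabulary", function(object, ...) standardGeneric("vocabulary"))
#' @export
setGeneric("docIds", function(object, ...) standardGeneric("docIds"))
#' @export
setGeneric("nTopics", function(object) standardGeneric("nTopics"))
#' @export
setGeneric("topicWordWeights", function(object) standardGeneric("topicWordWeights"))
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))
#' @export
setGeneric("modelClasses", function(object) standardGeneric("modelClasses"))
#' @export
setGeneric("edgeList", function(object) standardGeneric("edgeList"))
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @describeIn BowCorpus the sparse document-term count matrix.
#' @param object a BowCorpus.
#' @export
setMethod("counts", "BowCorpus", function(object, ...) object@counts)

#' @describeIn BowCorpus the vocabulary (column order of the counts).
#' @export
setMethod("vocabulary", "BowCorpus", function(object, ...) colnames(object@counts))

#' @describeIn BowCorpus the document ids (row order of the counts).
#' @export
setMethod("docIds", "BowCorpus", function(object, ...) rownames(object@counts))

#' @describeIn TopicModel the vocabulary the model was fitted on.
#' @param object a TopicModel.
#' @export
setMethod("vocabulary", "TopicModel", function(object, ...) object@vocabulary)

#' @describeIn TopicModel number of topics T.
#' @export
setMethod("nTopics", "TopicModel", function(object) nrow(object@params$beta))

#' @describeIn TopicModel the T x V topic-word weight matrix beta.
#' @export
setMethod("topicWordWeights", "TopicModel", function(object) {
  b <- object@params$beta
  colnames(b) <- object@vocabulary
  b
})

#' @describeIn TopicModel per-epoch mean training loss.
#' @export
setMethod("trainingLog", "TopicModel", function(object) object@trainingLog)

#' @describeIn SentimentModel per-epoch mean training loss.
#' @param object a SentimentModel.
#' @export
setMethod("trainingLog", "SentimentModel", function(object) object@trainingLog)

#' @describeIn SentimentModel the class labels in output order.
#' @export
setMethod("modelClasses", "SentimentModel", function(object) object@classes)

#' @describeIn TopicModel the label classes ("" if fitted unsupervised).
#' @export
setMethod("modelClasses", "TopicModel", function(object) object@classes)

#' @describeIn CooccurrenceNetwork the canonical edge table (u, v, weight).
#' @param object a CooccurrenceNetwork.
#' @export
setMethod("edgeList", "CooccurrenceNetwork", function(object) object@edges)

#' @describeIn CooccurrenceNetwork all node terms, isolated ones included.
#' @export
setMethod("networkNodes", "CooccurrenceNetwork", function(object) object@nodes)

## ---------------------------------------------------------------------- show

setMethod("show", "BowCorpus", function(object) {
  m <- object@counts
  cat("BowCorpus:", nrow(m), "documents x", ncol(m), "terms;",
      sum(m), "tokens\n")
  if (ncol(m)) cat("  top terms:",
    paste(head(colnames(m), 8), collapse = ", "), "\n")
})

setMethod("show", "SentimentLexicon", function(object) {
  cat("SentimentLexicon:", length(object@valence), "valence terms,",
      length(object@boosters), "boosters,",
      length(object@negators), "negators\n")
})

setMethod("show", "SentimentModel", function(object) {
  cfg <- object@config
  cat("SentimentModel (informed LSTM classifier)\n",
      " classes:", paste(object@classes, collapse = ", "), "\n",
      " prior-knowledge branch:",
      if (isTRUE(cfg$usePrior)) "enabled" else "ablated", "\n",
      " trained epochs:", length(object@trainingLog), "\n")
})

setMethod("show", "TopicModel", function(object) {
  cat("TopicModel (semi-supervised neural topic model)\n",
      " topics:", nTopics(object), " vocabulary:",
      length(object@vocabulary), "\n",
      " contextual fusion:",
      if ((object@config$contextualDim %||% 0) > 0) "enabled" else "disabled",
      "\n  trained epochs:", length(object@trainingLog), "\n")
})

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat("CooccurrenceNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
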