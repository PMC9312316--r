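## Small dense neural-net toolkit used by both models: Glorot init, Adam,
## activations. All randomness is drawn from R's global RNG so a single
## set.seed() at the head of a training run fixes everything.

.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# numerically stable row-wise softmax
.softmaxRows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# Adam state: list of moment pairs parallel to the parameter list
.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / b1t
    vhat <- state$v[[k]] / b2t
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# mean cross-entropy of softmax probabilities against integer class targets
.crossEntropy <- function(probs, target) {
  -mean(log(pmax(probs[cbind(seq_along(target), target)], 1e-12)))
}

#' Serialise a fitted model to a checkpoint file
#'
#' Writes a self-describing container (RDS) holding the configuration and
#' every parameter tensor; \code{readModel} restores it bit-exactly, so
#' predictions after a round trip are identical.
#'
#' @param model a \code{SentimentModel} or \code{TopicModel}.
#' @param path output file path.
#' @export
writeModel <- function(model, path) {
  stopifnot(methods::is(model, "SentimentModel") ||
            methods::is(model, "TopicModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname writeModel
#' @return \code{readModel}: the restored model object.
#' @export
readModel <- function(path) {
  obj <- readRDS(path)
  stopifnot(methods::is(obj, "SentimentModel") ||
            methods::is(obj, "TopicModel"))
  obj
}

# map token lists to integer id sequences (0 = out of vocabulary/padding)
.tokensToIds <- function(docs, vocab, maxLen) {
  lapply(docs, function(d) {
    ids <- match(d, vocab)
    ids <- ids[!is.na(ids)]
    if (length(ids) > maxLen) ids <- ids[seq_len(maxLen)]
    ids
  })
}

# pad a list of id sequences into a B x L matrix (0 = pad)
.padIds <- function(idsList, maxLen) {
  L <- max(1L, min(maxLen, max(c(1L, lengths(idsList)))))
  out <- matrix(0L, length(idsList), L)
  for (i in seq_along(idsList)) {
    v <- idsList[[i]]
    if (length(v)) out[i, seq_len(min(length(v), L))] <-
        v[seq_len(min(length(v), L))]
  }
  out
}
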