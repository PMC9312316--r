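## The informed neural network (INN) sentiment classifier: an LSTM encodes
## the token sequence; its final hidden state passes through a data head
## FCd; the lexicon-rule prior scores pass through a knowledge head FCk;
## the two representations are concatenated and a softmax layer FCs
## produces class probabilities. With usePrior = FALSE the knowledge branch
## is removed entirely, giving the vanilla-LSTM ablation with the identical
## data path.

#' Configuration for the informed sentiment classifier
#'
#' @param vocabSize vocabulary size V (embedding rows).
#' @param nClasses number of sentiment classes (>= 2).
#' @param embeddingDim word-embedding width.
#' @param hiddenDim LSTM hidden-state width (the h_i dimension).
#' @param fcDDim width of the data head FCd.
#' @param fcKDim width of the knowledge head FCk.
#' @param maxLen pad/truncate length for token sequences.
#' @param learningRate Adam learning rate.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed integer; fixes initialisation, shuffling, everything.
#' @param usePrior logical; FALSE ablates the knowledge branch (the
#'   vanilla-LSTM baseline with the same data architecture).
#' @return a named list.
#' @export
innConfig <- function(vocabSize, nClasses = 2, embeddingDim = 100,
                      hiddenDim = 128, fcDDim = 64, fcKDim = 16,
                      maxLen = 64, learningRate = 0.005, epochs = 10,
                      batchSize = 64, seed = 1L, usePrior = TRUE) {
  stopifnot(vocabSize >= 1, nClasses >= 2, embeddingDim >= 1,
            hiddenDim >= 1, fcDDim >= 1, fcKDim >= 1, maxLen >= 1)
  list(vocabSize = as.integer(vocabSize), nClasses = as.integer(nClasses),
       embeddingDim = as.integer(embeddingDim),
       hiddenDim = as.integer(hiddenDim), fcDDim = as.integer(fcDDim),
       fcKDim = as.integer(fcKDim), maxLen = as.integer(maxLen),
       learningRate = learningRate, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), seed = as.integer(seed),
       usePrior = isTRUE(usePrior))
}

.innInitParams <- function(cfg) {
  E <- cfg$embeddingDim; H <- cfg$hiddenDim
  p <- list(
    emb = .glorot(cfg$vocabSize, E),
    W_lstm = .glorot(E + H, 4 * H),
    b_lstm = c(rep(0, H), rep(1, H), rep(0, 2 * H)),  # forget-gate bias 1
    W_d = .glorot(H, cfg$fcDDim), b_d = rep(0, cfg$fcDDim))
  fused <- cfg$fcDDim
  if (cfg$usePrior) {
    p$W_k <- .glorot(3, cfg$fcKDim)
    p$b_k <- rep(0, cfg$fcKDim)
    fused <- fused + cfg$fcKDim
  }
  p$W_s <- .glorot(fused, cfg$nClasses)
  p$b_s <- rep(0, cfg$nClasses)
  p
}

# batched LSTM forward over a padded id matrix; returns final hidden state
# and, optionally, the per-step cache needed for backprop
.lstmForward <- function(ids, emb, W, b, H, cache = FALSE) {
  B <- nrow(ids); L <- ncol(ids)
  hprev <- matrix(0, B, H); cprev <- matrix(0, B, H)
  steps <- if (cache) vector("list", L) else NULL
  for (t in seq_len(L)) {
    idt <- ids[, t]
    m <- as.numeric(idt > 0L)
    x <- emb[pmax(idt, 1L), , drop = FALSE] * m
    A <- cbind(x, hprev) %*% W
    A <- sweep(A, 2, b, "+")
    i <- .sigmoid(A[, 1:H, drop = FALSE])
    f <- .sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
    o <- .sigmoid(A[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(A[, (3 * H + 1):(4 * H), drop = FALSE])
    ct <- f * cprev + i * g
    tc <- tanh(ct)
    ht <- o * tc
    cnew <- m * ct + (1 - m) * cprev
    hnew <- m * ht + (1 - m) * hprev
    if (cache) steps[[t]] <- list(idt = idt, m = m, x = x, i = i, f = f,
                                  o = o, g = g, ct = ct, tc = tc,
                                  hprev = hprev, cprev = cprev)
    hprev <- hnew; cprev <- cnew
  }
  list(h = hprev, steps = steps)
}

# backprop through time; dh is gradient wrt the final hidden state
.lstmBackward <- function(dh, steps, emb, W, H) {
  B <- nrow(dh); E <- ncol(emb)
  dW <- W * 0; db <- rep(0, 4 * H); dEmb <- emb * 0
  dc <- matrix(0, B, H)
  for (t in rev(seq_along(steps))) {
    s <- steps[[t]]
    m <- s$m
    dhm <- dh * m; dcm <- dc * m
    dhPass <- dh * (1 - m); dcPass <- dc * (1 - m)
    do <- dhm * s$tc
    dct <- dhm * s$o * (1 - s$tc^2) + dcm
    df <- dct * s$cprev
    di <- dct * s$g
    dg <- dct * s$i
    dcPrev <- dct * s$f + dcPass
    dA <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                do * s$o * (1 - s$o), dg * (1 - s$g^2))
    xh <- cbind(s$x, s$hprev)
    dW <- dW + crossprod(xh, dA)
    db <- db + colSums(dA)
    dxh <- dA %*% t(W)
    dx <- dxh[, 1:E, drop = FALSE] * m
    dhPrev <- dxh[, (E + 1):(E + H), drop = FALSE] + dhPass
    live <- which(s$m > 0)
    if (length(live)) {
      rows <- s$idt[live]
      agg <- rowsum(dx[live, , drop = FALSE], rows)
      ridx <- as.integer(rownames(agg))
      dEmb[ridx, ] <- dEmb[ridx, ] + agg
    }
    dh <- dhPrev; dc <- dcPrev
  }
  list(dW = dW, db = db, dEmb = dEmb)
}

#' Encode a token-id sequence into the final LSTM hidden state
#'
#' Feeds the sequence through the model's embedding and LSTM and returns
#' h_n, the final hidden state accumulating the whole sequence. An empty
#' sequence returns the all-zero vector (documented convention).
#'
#' @param model a \code{\link{SentimentModel}}.
#' @param ids integer vector of token ids (1-based into the vocabulary).
#' @return numeric vector of length hiddenDim.
#' @export
encodeSequence <- function(model, ids) {
  cfg <- model@config
  ids <- ids[ids > 0 & ids <= cfg$vocabSize]
  if (!length(ids)) return(rep(0, cfg$hiddenDim))
  if (length(ids) > cfg$maxLen) ids <- ids[seq_len(cfg$maxLen)]
  p <- model@params
  .lstmForward(matrix(as.integer(ids), 1), p$emb, p$W_lstm, p$b_lstm,
               cfg$hiddenDim)$h[1, ]
}

# full forward pass for a padded batch; prior is B x 3
.innForwardBatch <- function(p, cfg, ids, prior, cache = FALSE) {
  H <- cfg$hiddenDim
  ls <- .lstmForward(ids, p$emb, p$W_lstm, p$b_lstm, H, cache = cache)
  ad <- ls$h %*% p$W_d
  ad <- sweep(ad, 2, p$b_d, "+")
  zd <- pmax(ad, 0)
  if (cfg$usePrior) {
    ak <- prior %*% p$W_k
    ak <- sweep(ak, 2, p$b_k, "+")
    zk <- pmax(ak, 0)
    fused <- cbind(zd, zk)
  } else {
    zk <- NULL
    fused <- zd
  }
  logits <- fused %*% p$W_s
  logits <- sweep(logits, 2, p$b_s, "+")
  probs <- .softmaxRows(logits)
  list(probs = probs, fused = fused, zd = zd, zk = zk, h = ls$h,
       steps = ls$steps)
}

#' Class probabilities for token sequences with their prior scores
#'
#' @param model a \code{\link{SentimentModel}}.
#' @param docsIds list of integer token-id vectors.
#' @param prior numeric matrix n x 3 of prior scores (rows on the simplex);
#'   ignored when the model was built with \code{usePrior = FALSE}.
#' @return matrix n x nClasses of class probabilities (rows sum to 1).
#' @export
innForward <- function(model, docsIds, prior = NULL) {
  cfg <- model@config
  n <- length(docsIds)
  if (is.null(prior)) prior <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  stopifnot(nrow(prior) == n, ncol(prior) == 3)
  ids <- .padIds(.tokensToIds0(docsIds, cfg), cfg$maxLen)
  out <- .innForwardBatch(model@params, cfg, ids, prior)$probs
  colnames(out) <- model@classes
  out
}

.tokensToIds0 <- function(docsIds, cfg) {
  lapply(docsIds, function(v) {
    v <- as.integer(v)
    v[v > 0 & v <= cfg$vocabSize]
  })
}

#' Train the informed sentiment classifier
#'
#' Minimises softmax cross-entropy with Adam; fully deterministic given
#' \code{cfg$seed} (documents are canonically ordered by id before the
#' seeded shuffling, so input order is irrelevant). With
#' \code{cfg$usePrior = FALSE} the same run trains the vanilla-LSTM
#' ablation.
#'
#' @param docsIds list of integer token-id sequences (one per document).
#' @param prior numeric n x 3 matrix of prior scores.
#' @param labels factor or character vector of class labels (length n);
#'   at least two distinct classes must be present.
#' @param cfg an \code{\link{innConfig}}.
#' @param docnames optional document ids used for canonical ordering.
#' @return a \code{\link{SentimentModel}}.
#' @export
trainINN <- function(docsIds, prior, labels, cfg, docnames = NULL) {
  n <- length(docsIds)
  stopifnot(n >= 1, nrow(prior) == n, length(labels) == n)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2)
    stop("single-class corpus: the discrimination task is undefined")
  if (length(classes) > cfg$nClasses)
    stop("more classes present than cfg$nClasses")
  if (length(classes) < cfg$nClasses)
    classes <- c(classes,
                 paste0(".unused", seq_len(cfg$nClasses - length(classes))))
  y <- match(as.character(labels), classes)
  if (is.null(docnames)) docnames <- sprintf("doc%08d", seq_len(n))
  ord <- order(docnames)
  docsIds <- docsIds[ord]; prior <- prior[ord, , drop = FALSE]; y <- y[ord]

  set.seed(cfg$seed)
  p <- .innInitParams(cfg)
  trainLog <- numeric(0)
  if (cfg$epochs > 0) {
    opt <- .adamInit(p)
    idsAll <- .tokensToIds0(docsIds, cfg)
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / cfg$batchSize))
      epLoss <- 0
      for (bidx in batches) {
        ids <- .padIds(idsAll[bidx], cfg$maxLen)
        pr <- prior[bidx, , drop = FALSE]
        yb <- y[bidx]
        fw <- .innForwardBatch(p, cfg, ids, pr, cache = TRUE)
        B <- length(bidx)
        loss <- .crossEntropy(fw$probs, yb)
        epLoss <- epLoss + loss * B
        # backward
        dlogits <- fw$probs
        dlogits[cbind(seq_len(B), yb)] <- dlogits[cbind(seq_len(B), yb)] - 1
        dlogits <- dlogits / B
        g <- list()
        g$W_s <- crossprod(fw$fused, dlogits)
        g$b_s <- colSums(dlogits)
        dfused <- dlogits %*% t(p$W_s)
        dzd <- dfused[, seq_len(cfg$fcDDim), drop = FALSE] * (fw$zd > 0)
        g$W_d <- crossprod(fw$h, dzd)
        g$b_d <- colSums(dzd)
        if (cfg$usePrior) {
          dzk <- dfused[, cfg$fcDDim + seq_len(cfg$fcKDim),
                        drop = FALSE] * (fw$zk > 0)
          g$W_k <- crossprod(pr, dzk)
          g$b_k <- colSums(dzk)
        }
        dh <- dzd %*% t(p$W_d)
        lb <- .lstmBackward(dh, fw$steps, p$emb, p$W_lstm, cfg$hiddenDim)
        g$W_lstm <- lb$dW; g$b_lstm <- lb$db; g$emb <- lb$dEmb
        st <- .adamStep(p, g, opt, cfg$learningRate)
        p <- st$params; opt <- st$state
      }
      trainLog <- c(trainLog, epLoss / n)
    }
  }
  methods::new("SentimentModel", params = p, config = cfg,
               classes = classes, trainingLog = trainLog)
}

#' Predict sentiment classes for documents
#'
#' Batch-order independent; argmax labels with ties broken toward the
#' lower class index.
#'
#' @param model a \code{\link{SentimentModel}}.
#' @param docsIds list of integer token-id sequences.
#' @param prior numeric n x 3 prior-score matrix (may be NULL when the
#'   model is an ablation without the knowledge branch).
#' @return list with \code{probs} (n x nClasses matrix) and \code{labels}
#'   (character vector).
#' @export
predictSentiment <- function(model, docsIds, prior = NULL) {
  probs <- innForward(model, docsIds, prior)
  idx <- apply(probs, 1, which.max)   # which.max takes the first maximum
  list(probs = probs, labels = model@classes[idx])
}
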