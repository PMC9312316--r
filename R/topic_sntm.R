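## Semi-supervised neural topic model: a VAE over bag-of-words counts.
## Encoder: [bow, projected contextual embedding] -> softplus hidden ->
## (mu, log sigma^2). Latent: z = mu + sigma * zeta (reparameterisation).
## Decoder: theta = softmax(z); reconstruction logits theta %*% beta pushed
## through ONE softmax (product of experts, not a mixture of per-topic
## softmaxes). A classifier head on the latent turns partial labels into
## discriminative pressure on the topic space.

#' Configuration for the semi-supervised neural topic model
#'
#' @param nTopics number of topics T (>= 2; 5-50 is the usual search range).
#' @param vocabSize vocabulary size V.
#' @param hiddenDim encoder hidden width.
#' @param contextualDim width of the per-document contextual embedding;
#'   0 disables the fusion path entirely.
#' @param nClasses number of label classes (0 = unsupervised).
#' @param labelWeight multiplier on the classification loss term.
#' @param learningRate Adam learning rate.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param dropout dropout rate on the encoder hidden layer during training.
#' @param prodldaLikelihood logical. FALSE (default) trains the literal
#'   objective: L1 classification distance plus squared-L2 reconstruction
#'   of the L1-normalised count row plus the KL term. TRUE substitutes
#'   multinomial cross-entropy reconstruction and cross-entropy
#'   classification, the established practice for product-of-experts topic
#'   models; it trains markedly more stably and is what the recovery
#'   analyses use.
#' @param classifierInput what the classification head reads: "theta"
#'   (default) feeds the topic proportions softmax(z), tying label
#'   pressure directly to the topic axes; "z" feeds the raw latent sample
#'   (mu at inference). Both come from the latent representation; the
#'   theta coupling is what makes partial labels sharpen the topics
#'   themselves rather than an arbitrary rotation of the latent space.
#' @param seed integer seed fixing all randomness.
#' @return named list.
#' @export
sntmConfig <- function(nTopics, vocabSize, hiddenDim = 100,
                       contextualDim = 0, nClasses = 0, labelWeight = 1.0,
                       learningRate = 0.002, epochs = 50, batchSize = 64,
                       dropout = 0.2, prodldaLikelihood = FALSE,
                       classifierInput = c("theta", "z"),
                       seed = 1L) {
  classifierInput <- match.arg(classifierInput)
  stopifnot(nTopics >= 2, vocabSize >= 2, hiddenDim >= 1,
            contextualDim >= 0, nClasses >= 0, dropout >= 0, dropout < 1)
  list(nTopics = as.integer(nTopics), vocabSize = as.integer(vocabSize),
       hiddenDim = as.integer(hiddenDim),
       contextualDim = as.integer(contextualDim),
       nClasses = as.integer(nClasses), labelWeight = labelWeight,
       learningRate = learningRate, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), dropout = dropout,
       prodldaLikelihood = isTRUE(prodldaLikelihood),
       classifierInput = classifierInput,
       seed = as.integer(seed))
}

.sntmInitParams <- function(cfg) {
  V <- cfg$vocabSize; T <- cfg$nTopics; H <- cfg$hiddenDim
  inDim <- V + if (cfg$contextualDim > 0) V else 0
  p <- list(W1 = .glorot(inDim, H), b1 = rep(0, H),
            Wm = .glorot(H, T), bm = rep(0, T),
            Wv = .glorot(H, T), bv = rep(0, T),
            beta = matrix(stats::rnorm(T * V, 0, 0.02), T, V))
  if (cfg$contextualDim > 0) p$Wp <- .glorot(cfg$contextualDim, V)
  if (cfg$nClasses > 0) {
    p$Wc <- .glorot(T, cfg$nClasses)
    p$bc <- rep(0, cfg$nClasses)
  }
  p
}

# encoder forward: bow (B x V), ctx (B x C or NULL) -> mu, logvar (+cache)
.sntmEncode <- function(p, cfg, bow, ctx = NULL, dropMask = NULL) {
  x <- bow
  if (cfg$contextualDim > 0) {
    if (is.null(ctx)) stop("model expects contextual embeddings")
    x <- cbind(bow, ctx %*% p$Wp)
  }
  a1 <- sweep(x %*% p$W1, 2, p$b1, "+")
  h <- .softplus(a1)
  if (!is.null(dropMask)) h <- h * dropMask
  mu <- sweep(h %*% p$Wm, 2, p$bm, "+")
  logvar <- sweep(h %*% p$Wv, 2, p$bv, "+")
  list(mu = mu, logvar = logvar, h = h, a1 = a1, x = x)
}

#' Encode a document into its latent Gaussian posterior
#'
#' @param model a fitted \code{\link{TopicModel}}.
#' @param bowRow numeric vector of length V, nonnegative counts.
#' @param ctx optional contextual embedding vector (required if the model
#'   was fitted with contextual fusion).
#' @return list with \code{mu} and \code{sigma} (both length T; sigma > 0).
#' @export
encodeDocument <- function(model, bowRow, ctx = NULL) {
  cfg <- model@config
  stopifnot(length(bowRow) == cfg$vocabSize, all(bowRow >= 0))
  if (sum(bowRow) == 0 && is.null(ctx))
    stop("empty document: all-zero bag-of-words row and no context")
  ctxm <- if (!is.null(ctx)) matrix(ctx, 1) else NULL
  enc <- .sntmEncode(model@params, cfg, matrix(bowRow, 1), ctxm)
  list(mu = enc$mu[1, ], sigma = exp(0.5 * enc$logvar[1, ]))
}

#' Reparameterised latent sample
#'
#' z = mu + sigma * zeta, the change of variables that keeps gradients
#' flowing through the Gaussian sample.
#'
#' @param mu,sigma numeric vectors of length T (sigma >= 0).
#' @param zeta numeric vector of standard-normal draws, length T.
#' @return numeric vector z of length T.
#' @export
reparameterize <- function(mu, sigma, zeta) {
  stopifnot(length(mu) == length(zeta), length(sigma) == length(mu))
  mu + sigma * zeta
}

#' Decode a latent vector into a word distribution
#'
#' theta = softmax(z); the reconstruction is softmax(theta %*% beta):
#' topic-word weights are mixed in natural-parameter space and pushed
#' through a single softmax (product of experts), rather than averaging
#' per-topic distributions.
#'
#' @param model a \code{\link{TopicModel}}.
#' @param z numeric latent vector of length T.
#' @return numeric vector of length V on the simplex.
#' @export
decodeTopics <- function(model, z) {
  beta <- model@params$beta
  stopifnot(length(z) == nrow(beta))
  theta <- .softmaxRows(matrix(z, 1))
  drop(.softmaxRows(theta %*% beta))
}

#' Diagonal-Gaussian KL divergence to the standard normal
#'
#' Closed form: sum_j 0.5 * (mu_j^2 + sigma_j^2 - 1 - log sigma_j^2).
#'
#' @param mu,sigma numeric vectors (sigma strictly positive).
#' @return nonnegative scalar.
#' @examples
#' klTerm(0, 1)      # 0
#' klTerm(1, 1)      # 0.5
#' @export
klTerm <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  sum(0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma)))
}

#' The semi-supervised topic-model loss
#'
#' L = labelWeight * cls(y, yhat) + rec(d, dhat) + KL(mu, sigma), with the
#' classification term dropped for unlabelled documents. Under the literal
#' objective (default) cls is the L1 distance |y - yhat| against the
#' one-hot label and rec the squared L2 distance against the L1-normalised
#' count row; under \code{prodldaLikelihood} both are cross-entropies.
#'
#' @param d numeric vector: the document on the reconstruction scale
#'   (simplex-normalised counts for the literal objective, raw counts for
#'   the cross-entropy objective).
#' @param dhat reconstruction on the simplex, length V.
#' @param y integer class index or NA for an unlabelled document.
#' @param yhat class-probability vector (or NULL when unsupervised).
#' @param mu,sigma the latent posterior.
#' @param labelWeight multiplier on the classification term.
#' @param prodldaLikelihood use the cross-entropy form of both terms.
#' @return list with \code{total}, \code{cls}, \code{rec}, \code{kl}.
#' @export
sntmLoss <- function(d, dhat, y, yhat, mu, sigma, labelWeight = 1,
                     prodldaLikelihood = FALSE) {
  rec <- if (prodldaLikelihood) {
    -sum(d * log(pmax(dhat, 1e-12)))
  } else sum((d - dhat)^2)
  cls <- 0
  if (!is.null(yhat) && length(y) == 1 && !is.na(y)) {
    yone <- rep(0, length(yhat)); yone[y] <- 1
    cls <- if (prodldaLikelihood) -log(pmax(yhat[y], 1e-12)) else
      sum(abs(yone - yhat))
  }
  kl <- klTerm(mu, sigma)
  list(total = labelWeight * cls + rec + kl, cls = cls, rec = rec, kl = kl)
}

# loss and analytic gradients wrt mu and logvar for a single document with
# everything else held fixed; used for the finite-difference gradient check
# and shared by the training loop's backward pass (batched version below).
.sntmLossGradMuLogvar <- function(mu, logvar, zeta, beta, Wc, bc, d, y,
                                  labelWeight, prodlda,
                                  clsInput = "theta") {
  sigma <- exp(0.5 * logvar)
  z <- mu + sigma * zeta
  theta <- drop(.softmaxRows(matrix(z, 1)))
  logits <- drop(theta %*% beta)
  dhat <- drop(.softmaxRows(matrix(logits, 1)))
  yhat <- NULL
  clsIn <- if (clsInput == "theta") theta else z
  if (!is.null(Wc)) yhat <- drop(.softmaxRows(matrix(clsIn %*% Wc + bc, 1)))
  L <- sntmLoss(d, dhat, y, yhat, mu, sigma, labelWeight, prodlda)

  # backward
  if (prodlda) {
    dlogits <- sum(d) * dhat - d
  } else {
    dd <- 2 * (dhat - d)
    dlogits <- dhat * (dd - sum(dd * dhat))
  }
  dtheta <- drop(beta %*% dlogits)
  dz <- theta * (dtheta - sum(dtheta * theta))
  if (!is.null(yhat) && length(y) == 1 && !is.na(y)) {
    if (prodlda) {
      dly <- yhat; dly[y] <- dly[y] - 1
    } else {
      yone <- rep(0, length(yhat)); yone[y] <- 1
      ds <- sign(yhat - yone)
      dly <- yhat * (ds - sum(ds * yhat))
    }
    dIn <- drop(Wc %*% dly)
    if (clsInput == "theta") {
      dz <- dz + labelWeight * (theta * (dIn - sum(dIn * theta)))
    } else {
      dz <- dz + labelWeight * dIn
    }
  }
  dmu <- dz + mu
  dlogvar <- dz * zeta * 0.5 * sigma + 0.5 * (sigma^2 - 1)
  list(loss = L, dmu = dmu, dlogvar = dlogvar)
}

#' Fit the semi-supervised neural topic model
#'
#' Documents are canonically ordered by id, then minibatched with seeded
#' shuffling; Adam minimises the mean per-document loss. Labels may cover
#' any subset of documents (none = unsupervised); labels naming unknown
#' document ids are an error.
#'
#' @param bow a \code{\link{BowCorpus}}.
#' @param labels named character vector (names = document ids) covering any
#'   subset of documents, or NULL.
#' @param ctx optional numeric matrix of per-document contextual embeddings
#'   (rows aligned with and named by document ids).
#' @param cfg an \code{\link{sntmConfig}} (vocabSize must equal ncol(bow)).
#' @return a \code{\link{TopicModel}}.
#' @export
fitSNTM <- function(bow, labels = NULL, ctx = NULL, cfg) {
  m <- counts(bow)
  stopifnot(nrow(m) >= 1, ncol(m) == cfg$vocabSize)
  ids <- rownames(m)
  classes <- character(0)
  yIdx <- rep(NA_integer_, nrow(m))
  if (!is.null(labels) && length(labels)) {
    if (is.null(names(labels)) || !all(names(labels) %in% ids))
      stop("labels reference unknown document ids")
    classes <- sort(unique(as.character(labels)))
    if (cfg$nClasses == 0)
      cfg$nClasses <- length(classes)
    if (length(classes) > cfg$nClasses)
      stop("more label classes than cfg$nClasses")
    yIdx[match(names(labels), ids)] <- match(as.character(labels), classes)
  } else if (cfg$nClasses > 0) {
    classes <- paste0("class", seq_len(cfg$nClasses))
  }
  if (cfg$contextualDim > 0) {
    if (is.null(ctx)) stop("cfg$contextualDim > 0 but no ctx supplied")
    stopifnot(nrow(ctx) == nrow(m), ncol(ctx) == cfg$contextualDim)
    if (!is.null(rownames(ctx))) ctx <- ctx[ids, , drop = FALSE]
  }

  ord <- order(ids)
  m <- m[ord, , drop = FALSE]
  yIdx <- yIdx[ord]
  if (!is.null(ctx)) ctx <- ctx[ord, , drop = FALSE]
  X <- as.matrix(m)
  n <- nrow(X); V <- ncol(X); T <- cfg$nTopics
  rs <- rowSums(X)
  Xnorm <- X / pmax(rs, 1)          # L1-normalised rows (reconstruction d)
  prodlda <- cfg$prodldaLikelihood
  targetD <- if (prodlda) X else Xnorm

  set.seed(cfg$seed)
  p <- .sntmInitParams(cfg)
  opt <- .adamInit(p)
  trainLog <- numeric(0)
  hasCls <- cfg$nClasses > 0 && any(!is.na(yIdx))
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batchSize))
    epLoss <- 0
    for (bidx in batches) {
      B <- length(bidx)
      bowB <- X[bidx, , drop = FALSE]
      ctxB <- if (!is.null(ctx)) ctx[bidx, , drop = FALSE] else NULL
      dB <- targetD[bidx, , drop = FALSE]
      yB <- yIdx[bidx]
      dropMask <- NULL
      if (cfg$dropout > 0)
        dropMask <- matrix(stats::rbinom(B * cfg$hiddenDim, 1,
                                         1 - cfg$dropout),
                           B, cfg$hiddenDim) / (1 - cfg$dropout)
      enc <- .sntmEncode(p, cfg, bowB, ctxB, dropMask)
      sigma <- exp(0.5 * enc$logvar)
      zeta <- matrix(stats::rnorm(B * T), B, T)
      z <- enc$mu + sigma * zeta
      theta <- .softmaxRows(z)
      logits <- theta %*% p$beta
      dhat <- .softmaxRows(logits)

      ## loss pieces (per-doc sums, averaged over the batch at the end)
      if (prodlda) {
        recVec <- -rowSums(dB * log(pmax(dhat, 1e-12)))
        dlogits <- rowSums(dB) * dhat - dB
      } else {
        recVec <- rowSums((dB - dhat)^2)
        dd <- 2 * (dhat - dB)
        dlogits <- dhat * (dd - rowSums(dd * dhat))
      }
      klVec <- rowSums(0.5 * (enc$mu^2 + sigma^2 - 1 - enc$logvar))
      clsVec <- rep(0, B)
      g <- list()
      dthetaM <- dlogits %*% t(p$beta)
      dz <- theta * (dthetaM - rowSums(dthetaM * theta))
      g$beta <- crossprod(theta, dlogits)
      if (hasCls) {
        lab <- which(!is.na(yB))
        clsIn <- if (cfg$classifierInput == "theta") theta else z
        logc <- sweep(clsIn %*% p$Wc, 2, p$bc, "+")
        yhat <- .softmaxRows(logc)
        if (length(lab)) {
          if (prodlda) {
            clsVec[lab] <- -log(pmax(yhat[cbind(lab, yB[lab])], 1e-12))
            dlc <- yhat
            dlc[cbind(lab, yB[lab])] <- dlc[cbind(lab, yB[lab])] - 1
          } else {
            yone <- matrix(0, B, cfg$nClasses)
            yone[cbind(lab, yB[lab])] <- 1
            clsVec[lab] <- rowSums(abs(yone - yhat))[lab]
            ds <- sign(yhat - yone)
            dlc <- yhat * (ds - rowSums(ds * yhat))
          }
          dlc[setdiff(seq_len(B), lab), ] <- 0
          dlc <- dlc * cfg$labelWeight
          g$Wc <- crossprod(clsIn, dlc)
          g$bc <- colSums(dlc)
          dIn <- dlc %*% t(p$Wc)
          if (cfg$classifierInput == "theta") {
            dz <- dz + theta * (dIn - rowSums(dIn * theta))
          } else {
            dz <- dz + dIn
          }
        } else {
          g$Wc <- p$Wc * 0; g$bc <- p$bc * 0
        }
      }
      lossVec <- cfg$labelWeight * clsVec + recVec + klVec
      epLoss <- epLoss + sum(lossVec)

      dmu <- dz + enc$mu
      dlogvar <- dz * zeta * 0.5 * sigma + 0.5 * (sigma^2 - 1)
      # scale to batch mean
      sc <- 1 / B
      g$beta <- g$beta * sc
      if (!is.null(g$Wc)) { g$Wc <- g$Wc * sc; g$bc <- g$bc * sc }
      dmu <- dmu * sc; dlogvar <- dlogvar * sc
      dh <- dmu %*% t(p$Wm) + dlogvar %*% t(p$Wv)
      g$Wm <- crossprod(enc$h, dmu);     g$bm <- colSums(dmu)
      g$Wv <- crossprod(enc$h, dlogvar); g$bv <- colSums(dlogvar)
      if (!is.null(dropMask)) dh <- dh * dropMask
      da1 <- dh * .sigmoid(enc$a1)       # softplus'
      g$W1 <- crossprod(enc$x, da1)
      g$b1 <- colSums(da1)
      if (cfg$contextualDim > 0) {
        dx <- da1 %*% t(p$W1)
        dxc <- dx[, V + seq_len(V), drop = FALSE]
        g$Wp <- crossprod(ctxB, dxc)
      }
      st <- .adamStep(p, g, opt, cfg$learningRate)
      p <- st$params; opt <- st$state
    }
    trainLog <- c(trainLog, epLoss / n)
  }
  methods::new("TopicModel", params = p, config = cfg,
               vocabulary = colnames(m), classes = classes,
               trainingLog = trainLog)
}

#' Top-ranked terms of a topic
#'
#' The n terms with the largest topic-word weight, ties broken
#' lexicographically; n larger than V is clipped to V.
#'
#' @param model a \code{\link{TopicModel}}.
#' @param topic topic index in 1..T.
#' @param n number of terms.
#' @return character vector of terms.
#' @export
topWords <- function(model, topic, n = 10) {
  beta <- model@params$beta
  stopifnot(topic >= 1, topic <= nrow(beta))
  n <- min(n, ncol(beta))
  w <- beta[topic, ]
  ord <- order(-w, model@vocabulary)
  model@vocabulary[ord][seq_len(n)]
}

#' Topic proportions for documents
#'
#' theta = softmax(mu) of the encoded posterior; no sampling at inference.
#'
#' @param model a \code{\link{TopicModel}}.
#' @param bow a \code{\link{BowCorpus}} on the model's vocabulary (or a
#'   numeric matrix of counts).
#' @param ctx optional contextual embedding matrix.
#' @return numeric matrix n x T; rows on the simplex.
#' @export
inferTheta <- function(model, bow, ctx = NULL) {
  X <- if (methods::is(bow, "BowCorpus")) as.matrix(counts(bow)) else
    as.matrix(bow)
  cfg <- model@config
  stopifnot(ncol(X) == cfg$vocabSize)
  enc <- .sntmEncode(model@params, cfg, X, ctx)
  th <- .softmaxRows(enc$mu)
  rownames(th) <- rownames(X)
  th
}
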