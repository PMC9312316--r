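# small shared fitted model on a planted corpus (kept deliberately small;
# the full-scale recovery run lives in the acceptance suite)
sntmFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gen <- generateTopicCorpus(seed = 13, nDocs = 400, nTopics = 3,
                               vocabSize = 60, docLengthMean = 15,
                               labelFraction = 0.3)
    cfg <- sntmConfig(nTopics = 3, vocabSize = 60, epochs = 60,
                      prodldaLikelihood = TRUE, seed = 5)
    model <- fitSNTM(gen$bow, cfg = cfg)
    cache <<- list(gen = gen, model = model, cfg = cfg)
    cache
  }
})

test_that("encoding is deterministic with strictly positive sigma", {
  fx <- sntmFixture()
  row <- as.numeric(counts(fx$gen$bow)[1, ])
  e1 <- encodeDocument(fx$model, row)
  e2 <- encodeDocument(fx$model, row)
  expect_identical(e1, e2)
  expect_true(all(e1$sigma > 0))
  expect_error(encodeDocument(fx$model, rep(0, 60)), "empty document")
})

test_that("contextual fusion responds to the context vector", {
  gen <- generateTopicCorpus(seed = 2, nDocs = 120, nTopics = 3,
                             vocabSize = 40, docLengthMean = 10)
  ctx <- svdEmbeddings(gen$bow, dim = 5)
  cfg <- sntmConfig(nTopics = 3, vocabSize = 40, contextualDim = 5,
                    epochs = 3, prodldaLikelihood = TRUE, seed = 1)
  m <- fitSNTM(gen$bow, ctx = ctx, cfg = cfg)
  row <- as.numeric(counts(gen$bow)[1, ])
  eA <- encodeDocument(m, row, ctx[1, ])
  eB <- encodeDocument(m, row, ctx[2, ])
  expect_false(isTRUE(all.equal(eA$mu, eB$mu)))
  expect_error(encodeDocument(m, row), "contextual")
})

test_that("reparameterisation is the exact affine transform", {
  mu <- c(0.3, -1, 2); sigma <- c(0.5, 1, 2)
  expect_equal(reparameterize(mu, sigma, c(0, 0, 0)), mu)
  expect_equal(reparameterize(mu, sigma * 0, c(5, -5, 1)), mu)
  z <- reparameterize(mu, sigma, c(1, 2, -1))
  expect_equal(z, mu + sigma * c(1, 2, -1))
  # Monte-Carlo: mean of z over many draws concentrates on mu
  set.seed(4)
  n <- 1e5
  draws <- replicate(50, mu[1] + sigma[1] * mean(rnorm(n)))
  expect_lt(abs(mean(mu[1] + sigma[1] * rnorm(n)) - mu[1]),
            4 * sigma[1] / sqrt(n))
})

test_that("decoding gives a simplex vector, concentrates, and is
           permutation equivariant", {
  fx <- sntmFixture()
  z <- rnorm(3)
  d <- decodeTopics(fx$model, z)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_true(all(d >= 0))

  # constructed state: one dominant beta row + z on that topic
  m <- fx$model
  beta <- matrix(0, 3, 60)
  beta[2, 5:8] <- 10
  m@params$beta <- beta
  dhat <- decodeTopics(m, c(-10, 10, -10))
  expect_gt(sum(dhat[5:8]), 0.99)

  # permuting topics in beta and z leaves the reconstruction unchanged
  perm <- c(3, 1, 2)
  mP <- fx$model
  mP@params$beta <- fx$model@params$beta[perm, ]
  expect_equal(decodeTopics(fx$model, z), decodeTopics(mP, z[perm]),
               tolerance = 1e-12)
})

test_that("the KL term matches its closed form and is nonnegative", {
  expect_equal(klTerm(0, 1), 0)
  expect_equal(klTerm(1, 1), 0.5)
  expect_error(klTerm(0, 0), "positive")
  set.seed(7)
  for (i in 1:20) {
    expect_gte(klTerm(rnorm(4), exp(rnorm(4))), 0)
  }
})

test_that("the loss decomposes and drops the label term when unlabelled", {
  V <- 6
  d <- rep(1 / V, V)
  expect_equal(sntmLoss(d, d, 1L, c(1, 0), mu = 0, sigma = 1)$total, 0)
  # unlabelled: classification contributes nothing
  dhat <- c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1)
  lU <- sntmLoss(d, dhat, NA, c(0.2, 0.8), mu = c(1, 0), sigma = c(1, 1))
  expect_equal(lU$cls, 0)
  expect_equal(lU$total, lU$rec + lU$kl)
  # arithmetic oracle on fixed small tensors
  y <- 2L; yhat <- c(0.3, 0.7)
  l <- sntmLoss(d, dhat, y, yhat, mu = c(1, -1), sigma = c(0.5, 2),
                labelWeight = 2)
  expect_equal(l$rec, sum((d - dhat)^2))
  expect_equal(l$cls, abs(0 - 0.3) + abs(1 - 0.7))
  expect_equal(l$kl, 0.5 * (1 + 0.25 - 1 - log(0.25)) +
                 0.5 * (1 + 4 - 1 - log(4)))
  expect_equal(l$total, 2 * l$cls + l$rec + l$kl)
})

test_that("analytic loss gradients match finite differences", {
  set.seed(3)
  T <- 4; V <- 12; C <- 3
  beta <- matrix(rnorm(T * V), T, V)
  Wc <- matrix(rnorm(T * C), T, C); bc <- rnorm(C)
  mu <- rnorm(T); lv <- rnorm(T) * 0.3; zeta <- rnorm(T)
  d <- runif(V); d <- d / sum(d)
  for (prodlda in c(FALSE, TRUE)) {
    g <- infodemiR:::.sntmLossGradMuLogvar(mu, lv, zeta, beta, Wc, bc,
                                           d, 2L, 1.0, prodlda)
    for (j in seq_len(T)) {
      e <- rep(0, T); e[j] <- 1e-5
      numMu <- (infodemiR:::.sntmLossGradMuLogvar(mu + e, lv, zeta, beta,
                  Wc, bc, d, 2L, 1.0, prodlda)$loss$total -
                infodemiR:::.sntmLossGradMuLogvar(mu - e, lv, zeta, beta,
                  Wc, bc, d, 2L, 1.0, prodlda)$loss$total) / 2e-5
      expect_equal(g$dmu[j], numMu, tolerance = 1e-4)
      numLv <- (infodemiR:::.sntmLossGradMuLogvar(mu, lv + e, zeta, beta,
                  Wc, bc, d, 2L, 1.0, prodlda)$loss$total -
                infodemiR:::.sntmLossGradMuLogvar(mu, lv - e, zeta, beta,
                  Wc, bc, d, 2L, 1.0, prodlda)$loss$total) / 2e-5
      expect_equal(g$dlogvar[j], numLv, tolerance = 1e-4)
    }
  }
})

test_that("fitting is deterministic, order-invariant, and loss decreases", {
  gen <- generateTopicCorpus(seed = 6, nDocs = 200, nTopics = 3,
                             vocabSize = 40, docLengthMean = 10)
  cfg <- sntmConfig(nTopics = 3, vocabSize = 40, epochs = 10,
                    prodldaLikelihood = TRUE, seed = 9)
  m1 <- fitSNTM(gen$bow, cfg = cfg)
  m2 <- fitSNTM(gen$bow, cfg = cfg)
  expect_identical(m1@params$beta, m2@params$beta)
  expect_identical(trainingLog(m1), trainingLog(m2))

  # permuting document order does not change the trajectory
  perm <- sample(nrow(counts(gen$bow)))
  bowP <- new("BowCorpus", counts = counts(gen$bow)[perm, , drop = FALSE])
  m3 <- fitSNTM(bowP, cfg = cfg)
  expect_equal(trainingLog(m1), trainingLog(m3), tolerance = 1e-12)

  # mean loss over the last half of training is below the first half
  fx <- sntmFixture()
  tl <- trainingLog(fx$model)
  expect_lt(mean(tail(tl, length(tl) %/% 2)),
            mean(head(tl, length(tl) %/% 2)))

  expect_error(fitSNTM(gen$bow, labels = c(nosuchdoc = "t1"), cfg = cfg),
               "unknown document ids")
})

test_that("top words rank by weight with lexicographic ties", {
  fx <- sntmFixture()
  m <- fx$model
  beta <- matrix(0, 3, 60)
  beta[1, 3] <- 5                     # one-hot row
  beta[2, c(10, 11)] <- c(2, 2)       # tie
  m@params$beta <- beta
  vocab <- vocabulary(m)
  expect_equal(topWords(m, 1, 1), vocab[3])
  expect_equal(topWords(m, 2, 2), sort(vocab[c(10, 11)]))
  expect_length(topWords(m, 1, 999), 60)  # n clipped to V
  # brute-force argsort agreement on the fitted beta
  bw <- topicWordWeights(fx$model)
  for (j in 1:3) {
    ord <- order(-bw[j, ], colnames(bw))
    expect_equal(topWords(fx$model, j, 10), colnames(bw)[ord][1:10])
  }
})

test_that("inferred topic proportions are simplex and recover planted
           structure", {
  fx <- sntmFixture()
  th <- inferTheta(fx$model, fx$gen$bow)
  expect_equal(rowSums(th), rep(1, nrow(th)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(th, inferTheta(fx$model, fx$gen$bow))
  # a document made purely of topic-j anchor words lands on one topic that
  # is that topic's best match
  truthTop <- lapply(1:3, function(j)
    colnames(fx$gen$beta)[order(-fx$gen$beta[j, ])][1:10])
  fitTop <- lapply(1:3, function(j) topWords(fx$model, j, 10))
  # map fitted topic -> planted topic by top-word overlap
  best <- vapply(1:3, function(j)
    which.max(vapply(fitTop, function(f)
      length(intersect(truthTop[[j]], f)), numeric(1))), integer(1))
  doc <- rep(0, 60)
  doc[match(truthTop[[1]], vocabulary(fx$gen$bow))] <- 5
  thDoc <- inferTheta(fx$model, matrix(doc, 1))
  expect_equal(unname(which.max(thDoc[1, ])), best[1])
})

test_that("fitted topics are more diverse than a degenerate equal-beta
           model", {
  fx <- sntmFixture()
  fitTop <- lapply(1:3, function(j) topWords(fx$model, j, 10))
  degTop <- rep(list(fitTop[[1]]), 3)
  expect_equal(irbo(degTop), 0)
  expect_gte(irbo(fitTop), irbo(degTop))
})

test_that("topic-model checkpoints round-trip bit-exactly", {
  fx <- sntmFixture()
  path <- tempfile(fileext = ".rds")
  writeModel(fx$model, path)
  m2 <- readModel(path)
  expect_identical(inferTheta(fx$model, fx$gen$bow),
                   inferTheta(m2, fx$gen$bow))
})
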