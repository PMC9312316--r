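# Shared experiment drivers for the larger synthetic studies (also mirrored
# by scripts/acceptance.R, which cannot use test helpers).

# held-out accuracy of the informed classifier (or its ablation) on the
# imperfectly lexicon-aligned synthetic sentiment task
innHeldOutAccuracy <- function(seed, nTrain, usePrior, epochs = 3,
                               nTest = 2000, alignment = 0.8) {
  lex <- syntheticLexicon()
  tr <- generateSentimentCorpus(seed = seed, n = nTrain, lex = lex,
                                alignment = alignment)
  te <- generateSentimentCorpus(seed = seed + 5000, n = nTest, lex = lex,
                                alignment = alignment)
  docs <- preprocessText(c(tr$text, te$text))
  vocab <- buildVocabulary(docs, minCount = 1)
  cfg <- innConfig(vocabSize = length(vocab), seed = seed,
                   epochs = epochs, embeddingDim = 32, hiddenDim = 32,
                   fcDDim = 16, fcKDim = 8, maxLen = 16,
                   usePrior = usePrior)
  idsTr <- infodemiR:::.tokensToIds(docs[seq_len(nrow(tr))], vocab,
                                    cfg$maxLen)
  idsTe <- infodemiR:::.tokensToIds(docs[nrow(tr) + seq_len(nrow(te))],
                                    vocab, cfg$maxLen)
  m <- trainINN(idsTr, priorScores(tr$text, lex), tr$label, cfg,
                docnames = tr$id)
  pred <- predictSentiment(m, idsTe, priorScores(te$text, lex))
  mean(pred$labels == te$label)
}

# mean best-match top-10 word overlap between fitted and planted topics
topicRecoveryOverlap <- function(model, gen, n = 10) {
  Tn <- nrow(gen$beta)
  truthTop <- lapply(seq_len(Tn), function(j)
    colnames(gen$beta)[order(-gen$beta[j, ])][seq_len(n)])
  fitTop <- lapply(seq_len(nTopics(model)), function(j)
    topWords(model, j, n))
  mean(vapply(truthTop, function(tt)
    max(vapply(fitTop, function(f)
      length(intersect(tt, f)) / n, numeric(1))), numeric(1)))
}

# purity of the argmax-topic clustering against the planted classes
argmaxTopicPurity <- function(model, gen) {
  th <- inferTheta(model, gen$bow)
  asg <- apply(th, 1, which.max)
  gt <- apply(gen$theta, 1, which.max)[match(rownames(th),
                                             rownames(gen$theta))]
  keep <- !is.na(gt)
  sum(vapply(split(gt[keep], asg[keep]), function(g)
    max(table(g)), numeric(1))) / sum(keep)
}
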