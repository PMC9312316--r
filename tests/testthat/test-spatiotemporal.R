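streamFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateTweetStream(seed = 17,
                                                      nTotal = 600)
    cache
  }
})

test_that("discretisation partitions the stream into half-open slices", {
  rec <- streamFixture()
  for (gr in c("week", "day")) {
    sl <- discretize(rec, gr)
    expect_equal(nrow(sl), nrow(rec))           # every record in one slice
    expect_setequal(sl$id, rec$id)
    expect_true(all(table(sl$id) == 1))
  }
  # a record exactly on a Monday-midnight boundary opens its own week
  edge <- data.frame(id = "e1",
                     timestamp = as.POSIXct("2020-03-02 00:00:00",
                                            tz = "UTC"),
                     location = "x", stringsAsFactors = FALSE)
  sl <- discretize(edge, "week")
  expect_equal(sl$period, as.Date("2020-03-02"))
  # empty input -> empty map
  expect_equal(nrow(discretize(rec[0, ], "week")), 0)
})

test_that("week starts are Mondays and periods are consecutive", {
  rec <- streamFixture()
  sl <- discretize(rec, "week")
  expect_true(all(format(sl$period, "%u") == "1"))
  vt <- volumeTable(sl)
  expect_equal(as.numeric(diff(sort(unique(vt$period)))),
               rep(7, length(unique(vt$period)) - 1))
})

test_that("volume tables conserve the total and report empty slices as 0", {
  rec <- streamFixture()
  rec$location <- mapLocation(rec$location)
  sl <- discretize(rec, "week", byLocation = TRUE)
  vt <- volumeTable(sl)
  expect_equal(sum(vt$n), nrow(rec))
  # brute-force group-by agreement
  manual <- table(paste(sl$period, sl$location))
  got <- setNames(vt$n, paste(vt$period, vt$location))
  expect_equal(as.numeric(got[names(manual)]), as.numeric(manual))
  # the location grid contains cells with zero records
  expect_true(any(vt$n == 0))
})

test_that("sentiment ratios are in [0,1] with NA for empty slices", {
  fx <- tinyInnFixture()
  rec <- fx$corpus[1:80, ]
  sl <- discretize(rec, "week")
  sr <- sentimentRatio(rec, sl, fx$model, fx$vocab, fx$lex,
                       positive = "pos")
  nonEmpty <- sr$n > 0
  expect_true(all(sr$ratio[nonEmpty] >= 0 & sr$ratio[nonEmpty] <= 1))
  expect_true(all(is.na(sr$ratio[!nonEmpty])))
  # hand count of argmax labels for one slice
  docs <- preprocessText(rec$text)
  ids <- infodemiR:::.tokensToIds(docs, fx$vocab, fx$model@config$maxLen)
  pred <- predictSentiment(fx$model, ids, priorScores(rec$text, fx$lex))
  k <- paste(sl$period[1], sl$location[1])
  inSlice <- paste(sl$period, sl$location) == k
  expect_equal(sr$ratio[paste(sr$period, sr$location) == k],
               mean(pred$labels[match(sl$id[inSlice], rec$id)] == "pos"))
})

test_that("topic evolution reports simplex means and slice top terms", {
  gen <- generateTopicCorpus(seed = 23, nDocs = 300, nTopics = 3,
                             vocabSize = 60, docLengthMean = 12)
  cfg <- sntmConfig(nTopics = 3, vocabSize = 60, epochs = 30,
                    prodldaLikelihood = TRUE, seed = 2)
  model <- fitSNTM(gen$bow, cfg = cfg)
  rec <- data.frame(id = docIds(gen$bow),
                    timestamp = as.POSIXct("2020-02-03", tz = "UTC") +
                      runif(300, 0, 28 * 86400),
                    location = "all", stringsAsFactors = FALSE)
  sl <- discretize(rec, "week")
  ev <- topicEvolution(model, gen$bow, sl)
  th <- as.matrix(ev$meanTheta[, -(1:2)])
  expect_equal(rowSums(th), rep(1, nrow(th)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # single-slice input reproduces the global mean theta
  rec1 <- rec; rec1$timestamp <- as.POSIXct("2020-02-04", tz = "UTC")
  ev1 <- topicEvolution(model, gen$bow, discretize(rec1, "week"))
  expect_equal(nrow(ev1$meanTheta), 1)
  expect_equal(as.numeric(ev1$meanTheta[1, -(1:2)]),
               unname(colMeans(inferTheta(model, gen$bow))),
               tolerance = 1e-9)
  # per-slice term lists contain the topic's global top words
  expect_equal(sort(ev$topTerms[[1]][[1]]), sort(topWords(model, 1, 10)))
})

test_that("a planted regime switch shows up as declining early-topic
           prevalence", {
  rec <- generateTweetStream(seed = 41, nTotal = 1500)
  docs <- preprocessText(rec$text)
  names(docs) <- rec$id
  vocab <- buildVocabulary(docs, minCount = 2)
  bow <- bowCorpus(docs, vocab, ids = rec$id)
  keep <- Matrix::rowSums(counts(bow)) > 0
  bow <- new("BowCorpus", counts = counts(bow)[keep, , drop = FALSE])
  cfg <- sntmConfig(nTopics = 2, vocabSize = length(vocab), epochs = 40,
                    prodldaLikelihood = TRUE, seed = 3)
  model <- fitSNTM(bow, cfg = cfg)
  rec2 <- rec[rec$id %in% docIds(bow), ]
  sl <- discretize(rec2, "week")
  ev <- topicEvolution(model, bow, sl)
  th <- ev$meanTheta
  th <- th[order(th$period), ]
  # identify the early topic as the one with higher mean theta in the
  # first third of weeks; its prevalence must drop in the last third
  k <- nrow(th)
  first <- colMeans(th[1:max(1, k %/% 3), -(1:2), drop = FALSE])
  last <- colMeans(th[(k - k %/% 3 + 1):k, -(1:2), drop = FALSE])
  early <- which.max(first - last)
  expect_gt(first[early], last[early])
})

test_that("per-slice SBS series match direct per-slice computation", {
  rec <- streamFixture()
  docs <- preprocessText(rec$text)
  names(docs) <- rec$id
  sl <- discretize(rec, "week")
  res <- sbsOverTime(docs, sl, c("china", "lockdown"))
  expect_true(all(c("period", "concept", "sbs") %in% names(res)))
  # single-slice check against sbs() directly
  wk <- sort(unique(sl$period))[6]
  idsWk <- sl$id[sl$period == wk]
  dk <- docs[names(docs) %in% idsWk]
  net <- buildCooccurrence(dk)
  direct <- suppressWarnings(sbs(dk, net, c("china", "lockdown")))
  got <- res[res$period == wk, ]
  expect_equal(got$sbs, direct$sbs, tolerance = 1e-9)
  # a concept absent everywhere scores the per-slice standardised minimum
  resAbs <- sbsOverTime(docs, sl, c("china", "notaword"))
  for (p in unique(resAbs$period)) {
    chunk <- resAbs[resAbs$period == p, ]
    nodesSbs <- sbsOverTime(docs, sl[sl$period == p, , drop = FALSE],
                            unique(unlist(docs[names(docs) %in%
                              sl$id[sl$period == p]])))
    expect_lte(chunk$sbs[chunk$concept == "notaword"], min(nodesSbs$sbs))
  }
})

test_that("slice analyses are invariant to record order", {
  rec <- streamFixture()
  perm <- sample(nrow(rec))
  sl1 <- discretize(rec, "week")
  sl2 <- discretize(rec[perm, ], "week")
  v1 <- volumeTable(sl1); v2 <- volumeTable(sl2)
  expect_equal(v1, v2)
  docs <- preprocessText(rec$text); names(docs) <- rec$id
  r1 <- sbsOverTime(docs, sl1, "china")
  r2 <- sbsOverTime(docs[perm], sl2, "china")
  expect_equal(r1, r2, tolerance = 1e-12)
})
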