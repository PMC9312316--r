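# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use naive algorithms (exhaustive path
# enumeration, explicit per-pair counting, direct summation) so they share
# no code path with the functions under test.

# all simple paths between two nodes of an adjacency matrix (small graphs)
.oracleAllPaths <- function(adj, from, to) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(node, visited, path) {
    if (node == to) { paths[[length(paths) + 1]] <<- path; return() }
    for (nb in seq_len(n)) {
      if (adj[node, nb] && !visited[nb])
        walk(nb, `[<-`(visited, nb, TRUE), c(path, nb))
    }
  }
  walk(from, `[<-`(logical(n), from, TRUE), from)
  paths
}

# exhaustive shortest-path betweenness: for each unordered pair {j,k}
# enumerate ALL simple paths, keep the shortest, count those through c
oracleBetweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  if (n < 3) return(btw)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    paths <- .oracleAllPaths(adj, j, k)
    if (!length(paths)) next
    lens <- lengths(paths)
    sp <- paths[lens == min(lens)]
    njk <- length(sp)
    for (c in seq_len(n)) {
      if (c == j || c == k) next
      through <- sum(vapply(sp, function(p) c %in% p, logical(1)))
      btw[c] <- btw[c] + through / njk
    }
  }
  btw
}

# random connected-ish undirected graph as adjacency matrix with node names
randomGraphAdj <- function(nNodes, pEdge = 0.4) {
  adj <- matrix(0L, nNodes, nNodes)
  for (i in seq_len(nNodes - 1)) for (j in (i + 1):nNodes)
    if (stats::runif(1) < pEdge) adj[i, j] <- adj[j, i] <- 1L
  dimnames(adj) <- list(paste0("n", seq_len(nNodes)),
                        paste0("n", seq_len(nNodes)))
  adj
}

adjToNetwork <- function(adj) {
  nodes <- rownames(adj)
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(u = nodes[idx[, 1]], v = nodes[idx[, 2]],
                      weight = rep(1L, nrow(idx)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  new("CooccurrenceNetwork", nodes = nodes, edges = edges)
}

# direct per-pair NPMI on token lists (document co-occurrence, eps smoothing)
oracleNpmi <- function(topics, docs, epsilon = 1e-12) {
  N <- length(docs)
  docSets <- lapply(docs, unique)
  pdoc <- function(w) sum(vapply(docSets, function(d) w %in% d,
                                 logical(1))) / N
  pjoint <- function(wi, wj) sum(vapply(docSets, function(d)
    wi %in% d && wj %in% d, logical(1))) / N
  perTopic <- vapply(topics, function(tw) {
    tw <- unique(tw)
    vals <- c()
    for (a in seq_len(length(tw) - 1)) for (b in (a + 1):length(tw)) {
      pi <- max(pdoc(tw[a]), epsilon)
      pj <- max(pdoc(tw[b]), epsilon)
      pij <- pjoint(tw[a], tw[b])
      vals <- c(vals, (log(pij + epsilon) - log(pi * pj)) /
                  (-log(pij + epsilon)))
    }
    mean(vals)
  }, numeric(1))
  mean(perTopic)
}

# direct truncated-summation RBO for equal-length lists
oracleRboEqual <- function(a, b, p) {
  k <- length(a)
  stopifnot(length(b) == k)
  X <- vapply(seq_len(k), function(d)
    length(intersect(a[seq_len(d)], b[seq_len(d)])), numeric(1))
  (1 - p) / p * sum(X / seq_len(k) * p^seq_len(k)) + X[k] / k * p^k
}

# confusion-matrix metrics computed longhand
oracleClsMetrics <- function(labels, pred, positive) {
  tp <- sum(pred == positive & labels == positive)
  fp <- sum(pred == positive & labels != positive)
  fn <- sum(pred != positive & labels == positive)
  tn <- sum(pred != positive & labels != positive)
  acc <- (tp + tn) / length(labels)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  list(accuracy = acc, precision = prec, recall = rec,
       f1 = 2 * prec * rec / (prec + rec))
}

# shared tiny fixtures -------------------------------------------------------

tinyTweetDf <- function() {
  data.frame(
    id = paste0("t", 1:5),
    text = c("Stay HOME!!! https://t.co/x", "great news about recovery",
             "not great news today", "panic buying toilet paper",
             "lockdown extended again"),
    timestamp = as.POSIXct("2020-03-02 10:00:00", tz = "UTC") +
      c(0, 3600, 86400 * 3, 86400 * 8, 86400 * 15),
    location = c("Sydney", "melbourne", "Queensland", "australia", "mars"),
    label = c(NA, "pos", "neg", "neg", "neg"),
    stringsAsFactors = FALSE)
}

# a small trained INN on a lexicon-aligned corpus; memoised per session
tinyInnFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lex <- syntheticLexicon()
    tr <- generateSentimentCorpus(seed = 11, n = 200, lex = lex,
                                  alignment = 1)
    docs <- preprocessText(tr$text)
    vocab <- buildVocabulary(docs, minCount = 1)
    cfg <- innConfig(vocabSize = length(vocab), seed = 3, epochs = 3,
                     embeddingDim = 16, hiddenDim = 16, fcDDim = 8,
                     fcKDim = 4, maxLen = 16)
    ids <- infodemiR:::.tokensToIds(docs, vocab, cfg$maxLen)
    model <- trainINN(ids, priorScores(tr$text, lex), tr$label, cfg,
                      docnames = tr$id)
    cache <<- list(model = model, vocab = vocab, lex = lex, corpus = tr,
                   ids = ids)
    cache
  }
})
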