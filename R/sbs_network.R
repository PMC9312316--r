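## Word co-occurrence networks and the Semantic Brand Score:
## SBS(c) = z(PREV(c)) + z(DIV(c)) + z(CON(c)), standardised over all
## network nodes. PREV is the total mention count, DIV the degree, CON the
## (unnormalised, undirected) shortest-path betweenness.

#' Build a term co-occurrence network from preprocessed documents
#'
#' An edge (u, v) is present iff the two distinct terms co-occur in at
#' least \code{minEdgeWeight} documents; its weight is the number of
#' co-occurring documents. The co-occurrence unit is the whole document
#' (tweets are short); \code{window} restricts it to pairs of tokens at
#' distance < window for longer documents.
#'
#' @param docs list of token vectors.
#' @param minEdgeWeight minimum document co-occurrence count (default 1).
#' @param window token-distance window; Inf (default) = whole document.
#' @return a \code{\link{CooccurrenceNetwork}}.
#' @export
buildCooccurrence <- function(docs, minEdgeWeight = 1, window = Inf) {
  vocab <- sort(unique(unlist(docs)))
  if (!length(vocab))
    return(methods::new("CooccurrenceNetwork", nodes = character(),
                        edges = data.frame(u = character(),
                                           v = character(),
                                           weight = integer())))
  pairCount <- new.env(hash = TRUE, parent = emptyenv())
  for (d in docs) {
    if (length(d) < 2) next
    if (is.finite(window)) {
      prs <- character(0)
      for (i in seq_len(length(d) - 1)) {
        jmax <- min(length(d), i + window - 1)
        if (jmax <= i) next
        for (j in (i + 1):jmax) {
          if (d[i] == d[j]) next
          a <- min(d[i], d[j]); b <- max(d[i], d[j])
          prs <- c(prs, paste(a, b, sep = "\r"))
        }
      }
      prs <- unique(prs)
    } else {
      u <- sort(unique(d))
      if (length(u) < 2) next
      idx <- utils::combn(length(u), 2)
      prs <- paste(u[idx[1, ]], u[idx[2, ]], sep = "\r")
    }
    for (k in prs)
      assign(k, (if (exists(k, envir = pairCount)) get(k, envir = pairCount)
                 else 0L) + 1L, envir = pairCount)
  }
  keys <- ls(pairCount)
  if (length(keys)) {
    w <- vapply(keys, get, integer(1), envir = pairCount)
    keep <- w >= minEdgeWeight
    keys <- keys[keep]; w <- w[keep]
    uv <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    edges <- data.frame(u = uv[, 1], v = uv[, 2], weight = as.integer(w),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(u = character(), v = character(),
                        weight = integer())
  }
  methods::new("CooccurrenceNetwork", nodes = vocab, edges = edges)
}

.asIgraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net@nodes), name = net@nodes)
  if (nrow(net@edges))
    g <- igraph::add_edges(g, rbind(net@edges$u, net@edges$v))
  g
}

#' Prevalence of a concept: total mention count
#'
#' @param docs list of token vectors (the corpus the network came from).
#' @param concepts character vector of concept terms.
#' @return named integer vector of total token counts (0 if absent).
#' @export
prevalence <- function(docs, concepts) {
  toks <- unlist(docs, use.names = FALSE)
  vapply(stats::setNames(concepts, concepts),
         function(c) sum(toks == c), numeric(1))
}

#' Diversity of a concept: degree in the co-occurrence network
#'
#' @param net a \code{\link{CooccurrenceNetwork}}.
#' @param concepts character vector of concept terms.
#' @return named numeric vector of degrees (0 for absent/isolated nodes).
#' @export
diversity <- function(net, concepts) {
  e <- net@edges
  vapply(stats::setNames(concepts, concepts),
         function(c) sum(e$u == c) + sum(e$v == c), numeric(1))
}

#' Connectivity of a concept: unnormalised betweenness centrality
#'
#' Sum over unordered node pairs {j, k} (both different from c) of the
#' fraction of shortest paths between j and k that pass through c;
#' unweighted shortest paths, disconnected pairs contribute 0.
#'
#' @param net a \code{\link{CooccurrenceNetwork}}.
#' @param concepts character vector of concept terms (default: all nodes).
#' @return named numeric vector.
#' @export
connectivity <- function(net, concepts = networkNodes(net)) {
  out <- stats::setNames(rep(0, length(concepts)), concepts)
  if (!length(net@nodes)) return(out)
  g <- .asIgraph(net)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = FALSE)
  hit <- concepts %in% names(btw)
  out[concepts[hit]] <- btw[concepts[hit]]
  out
}

#' Semantic Brand Score
#'
#' Each component is standardised as (x - mean) / sd where mean and sd are
#' taken over ALL network nodes (sample sd); the SBS is the sum of the
#' three standardised components. A component that is constant over the
#' network (sd = 0, e.g. a single-node network) contributes 0, with a
#' warning. Concepts absent from the network get raw components 0,
#' standardised against the node population, i.e. the slice minimum.
#'
#' @param docs list of token vectors (for prevalence counts).
#' @param net a \code{\link{CooccurrenceNetwork}} built from those docs.
#' @param concepts character vector of query concepts.
#' @return data.frame with columns concept, prev, div, con, z_prev, z_div,
#'   z_con, sbs; attribute \code{nodeStats} holds the component means/sds.
#' @export
sbs <- function(docs, net, concepts) {
  nodes <- networkNodes(net)
  prevAll <- prevalence(docs, nodes)
  divAll <- diversity(net, nodes)
  conAll <- connectivity(net, nodes)
  zfun <- function(allv, qv, name) {
    mu <- if (length(allv)) mean(allv) else 0
    sdv <- if (length(allv) > 1) stats::sd(allv) else 0
    if (!is.finite(sdv) || sdv == 0) {
      warning("degenerate ", name,
              " (zero spread over network nodes): component contributes 0")
      return(list(z = rep(0, length(qv)), mean = mu, sd = sdv))
    }
    list(z = (qv - mu) / sdv, mean = mu, sd = sdv)
  }
  qPrev <- prevalence(docs, concepts)
  qDiv <- diversity(net, concepts)
  qCon <- connectivity(net, concepts)
  zp <- zfun(prevAll, qPrev, "prevalence")
  zd <- zfun(divAll, qDiv, "diversity")
  zc <- zfun(conAll, qCon, "connectivity")
  out <- data.frame(concept = concepts, prev = unname(qPrev),
                    div = unname(qDiv), con = unname(qCon),
                    z_prev = unname(zp$z), z_div = unname(zd$z),
                    z_con = unname(zc$z),
                    stringsAsFactors = FALSE)
  out$sbs <- out$z_prev + out$z_div + out$z_con
  attr(out, "nodeStats") <- data.frame(
    component = c("prev", "div", "con"),
    mean = c(zp$mean, zd$mean, zc$mean),
    sd = c(zp$sd, zd$sd, zc$sd))
  out
}

#' Export a co-occurrence network as an edge-list CSV
#'
#' @param net a \code{\link{CooccurrenceNetwork}}.
#' @param path output CSV path (columns u, v, weight).
#' @export
writeEdgeList <- function(net, path) {
  utils::write.csv(net@edges, path, row.names = FALSE)
  invisible(path)
}
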