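# Shared fixtures and independent oracles, built in code.

# --- small graph builders -------------------------------------------------

edgeDf <- function(from, to, weight) {
  data.frame(from = from, to = to, weight = weight, stringsAsFactors = FALSE)
}

writeEdgeFile <- function(edf, header = FALSE) {
  f <- tempfile(fileext = ".tsv")
  lines <- sprintf("%s\t%s\t%s", edf$from, edf$to,
                   format(edf$weight, trim = TRUE))
  if (header) lines <- c("gene_a\tgene_b\tweight", lines)
  writeLines(lines, f)
  f
}

networkFromEdges <- function(edf, floor = 0.1) {
  loadNetwork(writeEdgeFile(edf), weightFloor = floor)
}

# path A-B-C-... with constant weight
pathNetwork <- function(genes, weight = 0.5) {
  n <- length(genes)
  networkFromEdges(edgeDf(genes[-n], genes[-1], rep(weight, n - 1)))
}

# a module covering a whole small network
wholeModule <- function(net, kind = "DGN") {
  buildModule(net, nodes(net), kind = kind)
}

# random connected-ish weighted graph for oracle comparisons
randomNetwork <- function(nNodes, pEdge = 0.35, minW = 0.15, maxW = 1) {
  repeat {
    pairs <- t(combn(nNodes, 2))
    keep <- runif(nrow(pairs)) < pEdge
    if (sum(keep) < 1) next
    edf <- edgeDf(sprintf("n%02d", pairs[keep, 1]),
                  sprintf("n%02d", pairs[keep, 2]),
                  runif(sum(keep), minW, maxW))
    net <- tryCatch(networkFromEdges(edf), error = function(e) NULL)
    if (!is.null(net) && numNodes(net) >= 3) return(net)
  }
}

# --- independent oracles --------------------------------------------------

# brute-force O(n^3) Adamic-Adar: explicit loop over ordered pairs and
# common neighbors, sharing only the documented denominator convention
bruteAdamicAdar <- function(module, strengthFloor = 2) {
  ed <- edges(subnetwork(module))
  genes <- sort(members(module))
  adj <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
  for (i in seq_len(nrow(ed))) {
    adj[ed$from[i], ed$to[i]] <- ed$weight[i]
    adj[ed$to[i], ed$from[i]] <- ed$weight[i]
  }
  strength <- rowSums(adj)
  out <- stats::setNames(numeric(length(genes)), genes)
  for (x in genes) for (y in genes) {
    if (x == y) next
    sxy <- 0
    for (z in genes) {
      if (adj[x, z] > 0 && adj[y, z] > 0)
        sxy <- sxy + 1 / log(max(strength[z], strengthFloor))
    }
    out[x] <- out[x] + sxy
  }
  out
}

# dense linear-solve PageRank oracle: x = (1-d)/n 1 + d P^T x solved
# exactly, no power iteration
densePagerank <- function(module, damping = 0.75) {
  ed <- edges(subnetwork(module))
  genes <- sort(members(module))
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(nrow(ed))) {
    A[ed$from[i], ed$to[i]] <- ed$weight[i]
    A[ed$to[i], ed$from[i]] <- ed$weight[i]
  }
  s <- rowSums(A)
  P <- A / ifelse(s > 0, s, 1)
  x <- solve(diag(n) - damping * t(P), rep((1 - damping) / n, n))
  stats::setNames(x / sum(x), genes)
}

# Mann-Whitney AUC oracle: P(reference gene ranked above non-reference),
# by explicit pair counting over positions
mannWhitneyAuc <- function(ranked, reference) {
  pos <- which(ranked %in% reference)
  neg <- which(!ranked %in% reference)
  mean(outer(pos, neg, "<"))
}
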