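# Independent oracles and small fixture builders used across the suite.
# Each oracle is deliberately naive (enumeration, brute force) and shares no
# code with the implementation paths it checks.

# Upper-tail hypergeometric probability by direct summation of counting
# ratios (no distribution functions).
oracleHyperUpper <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (k > min(n, K)) return(0)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Two-sided Fisher p by enumeration over all tables with the observed
# margins; tables no more probable than the observed one (with the
# conventional 1e-7 relative slack) contribute.
oracleFisherTwoSided <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  pObs <- probs[x == tab[1, 1]]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Coreness by literal iterative peeling on an adjacency matrix.
oracleCoreness <- function(graph) {
  adj <- as.matrix(igraph::as_adjacency_matrix(graph))
  n <- nrow(adj)
  core <- setNames(integer(n), rownames(adj))
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    k <- k + 1L
    repeat {
      deg <- rowSums(adj[, alive, drop = FALSE])[alive]
      peel <- names(deg)[deg < k]
      if (length(peel) == 0) break
      core[peel] <- k - 1L
      alive[match(peel, rownames(adj))] <- FALSE
    }
  }
  core
}

# All set partitions of n items as restricted growth strings (0-based).
allPartitions <- function(n) {
  out <- list()
  rec <- function(rgs, mx) {
    if (length(rgs) == n) {
      out[[length(out) + 1L]] <<- rgs
      return(invisible())
    }
    for (v in 0:(mx + 1L)) rec(c(rgs, v), max(mx, v))
  }
  rec(0L, 0L)
  out
}

# Exhaustive modularity maximum over every partition of a small graph.
oracleBestModularity <- function(graph) {
  parts <- allPartitions(igraph::vcount(graph))
  max(vapply(parts, function(p) igraph::modularity(graph, p + 1L),
             numeric(1)))
}

ari <- function(a, b) igraph::compare(a, b, method = "adjusted.rand")

# Small named graphs.
mkGraph <- function(el, n) {
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}
cliqueEdges <- function(k, offset = 0) t(combn(offset + seq_len(k), 2L))

twoTriangles <- function() mkGraph(rbind(cliqueEdges(3), cliqueEdges(3, 3)), 6)
twoTrianglesBridged <- function()
  mkGraph(rbind(cliqueEdges(3), cliqueEdges(3, 3), c(1, 4)), 6)

# A MatchedBackground wrapper for calibration scenarios where covariate
# balance is true by construction.
trivialPool <- function(poolGenes, target) {
  new("MatchedBackground", genes = setdiff(poolGenes, target),
      target = target, balance = c(cds_length = 1),
      covariates = "cds_length", threshold = 0.05)
}
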