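#' Read an interaction network from a two-column edge list
#'
#' Parses a tab- or whitespace-delimited edge list (BioGrid-tab-like: two
#' interactor symbol columns, extra columns ignored) into an undirected
#' simple graph. Self-loops are dropped, duplicate and reversed-duplicate
#' edges collapsed, and isolated nodes (nodes left without any edge, e.g.
#' nodes that only self-interacted) removed.
#'
#' @param path Path to the edge-list file.
#' @param columns Integer vector of length 2: which columns hold the two
#'   interactor symbols (default first two).
#' @param header `"auto"` to skip a first line whose selected fields look
#'   like column labels (`gene`, `symbol`, `interactor`...), or `TRUE` /
#'   `FALSE` to force.
#' @param directedInputOk Edges are read as unordered pairs regardless of
#'   input order; set to `FALSE` to error if both orientations of a pair are
#'   present (strict undirected input).
#'
#' @return An [igraph::igraph] undirected simple graph whose vertex names
#'   are the gene symbols.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB", "B\tA", "C\tC", "A\tB"), tf)
#' g <- readEdgeList(tf)
#' igraph::vcount(g)  # 2
readEdgeList <- function(path, columns = c(1L, 2L), header = "auto",
                         directedInputOk = TRUE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("edge-list file is empty: ", path)

  fields <- strsplit(trimws(lines), "[\t ]+")
  firstLine <- 1L
  if (identical(header, TRUE)) {
    firstLine <- 2L
  } else if (identical(header, "auto") && length(fields[[1L]]) >= max(columns)) {
    lab <- tolower(fields[[1L]][columns])
    if (any(grepl("gene|symbol|interactor|protein|node", lab))) firstLine <- 2L
  }
  if (firstLine > length(lines)) stop("edge-list file holds only a header: ", path)

  idx <- seq(firstLine, length(fields))
  bad <- idx[vapply(fields[idx], length, 1L) < max(columns)]
  if (length(bad) > 0L)
    stop(sprintf("malformed edge-list line %d in %s: fewer than %d fields",
                 bad[1L], path, max(columns)))
  a <- vapply(fields[idx], `[[`, "", columns[1L])
  b <- vapply(fields[idx], `[[`, "", columns[2L])

  if (!directedInputOk) {
    key <- paste(a, b, sep = "\r")
    rev <- paste(b, a, sep = "\r")
    both <- key[key %in% rev & a != b]
    if (length(both) > 0L)
      stop("both orientations present for ", length(both),
           " pairs but directedInputOk = FALSE")
  }

  keep <- a != b
  nSelf <- sum(!keep)
  # canonical unordered pair, then dedup
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  g <- igraph::graph_from_edgelist(cbind(lo[!dup], hi[!dup]), directed = FALSE)
  message(sprintf(
    "readEdgeList: %d nodes, %d edges (%d self-loops dropped, %d duplicate edges collapsed)",
    igraph::vcount(g), igraph::ecount(g), nSelf, sum(dup)))
  g
}

#' Write an interaction network as a two-column edge list
#'
#' @param graph An undirected igraph with named vertices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  lo <- pmin(el[, 1L], el[, 2L])
  hi <- pmax(el[, 1L], el[, 2L])
  ord <- order(lo, hi)
  writeLines(c("interactor_a\tinteractor_b",
               paste(lo[ord], hi[ord], sep = "\t")), path)
  invisible(path)
}

.checkInteractome <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("not an igraph object")
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  if (is.null(igraph::V(graph)$name)) stop("graph vertices must be named")
  invisible(graph)
}

#' Newman--Girvan modularity of a partition
#'
#' Q = sum over modules c of e_c / m - (d_c / 2m)^2, where m is the total
#' edge count, e_c the number of intra-module edges and d_c the degree sum
#' of module c. Q = 0 for the trivial one-module partition.
#'
#' @param partition A [ModulePartition] (or a named integer/character
#'   assignment vector) covering every node of `graph`.
#' @param graph The undirected graph the partition refers to.
#' @return Modularity Q in [-1, 1].
#' @export
modularityScore <- function(partition, graph) {
  .checkInteractome(graph)
  assign <- if (is(partition, "ModulePartition")) partition@assignment else partition
  nodes <- igraph::V(graph)$name
  miss <- setdiff(nodes, names(assign))
  if (length(miss) > 0L)
    stop("partition misses ", length(miss), " graph node(s), e.g. ", miss[1L])
  mem <- as.integer(factor(assign[nodes]))
  igraph::modularity(graph, mem)
}

# Relabel an arbitrary membership vector into contiguous 0-based ids in
# order of first appearance (deterministic given vertex order).
.canonicalIds <- function(mem) {
  as.integer(factor(mem, levels = unique(mem))) - 1L
}

#' First-level modularity-maximizing partition (multilevel heuristic)
#'
#' Runs the multilevel (Louvain) modularity-maximization heuristic and keeps
#' the partition after the *first* complete level -- the finest partition
#' after the first local-move + aggregation cycle, without further grouping
#' of small modules into larger ones. Because the greedy local moves depend
#' on node order, the heuristic is restarted `nRestarts` times under seeded
#' node orders and the first-level partition with the highest modularity is
#' returned; this removes the order-dependence of single runs while staying
#' strictly first-level.
#'
#' @param graph Undirected simple graph with named vertices.
#' @param seed Integer seed; the result is deterministic given `seed`.
#' @param nRestarts Number of seeded restarts (default 10).
#' @return A [ModulePartition] with `level = 1`, `q` populated.
#' @export
louvainPartition <- function(graph, seed, nRestarts = 10L) {
  .checkInteractome(graph)
  seed <- as.integer(seed)
  best <- NULL
  bestQ <- -Inf
  for (r in seq_len(nRestarts)) {
    set.seed(deriveSeed(seed, r))
    cl <- igraph::cluster_louvain(graph)
    mem <- if (is.matrix(cl$memberships)) cl$memberships[1L, ] else
      igraph::membership(cl)
    q <- igraph::modularity(graph, mem)
    if (q > bestQ) {
      bestQ <- q
      best <- mem
    }
  }
  assign <- setNames(.canonicalIds(best), igraph::V(graph)$name)
  new("ModulePartition", assignment = assign, q = bestQ,
      level = 1L, seed = seed)
}

#' Degree-preserving rewiring of a network
#'
#' Randomizes edges by repeated double-edge swaps, keeping every node's
#' degree fixed and rejecting swaps that would create self-loops or
#' duplicate edges -- the standard topological null model for modularity
#' testing.
#'
#' @param graph Undirected simple graph with >= 2 edges.
#' @param nSwapMultiplier Attempted swaps = `ceiling(nSwapMultiplier *
#'   ecount(graph))` (default 10).
#' @param seed Integer seed.
#' @return A rewired igraph with the identical degree multiset. If no swap
#'   succeeded (no legal swap exists, e.g. a star), the input is returned
#'   unchanged with a warning.
#' @export
degreePreservingRewire <- function(graph, seed, nSwapMultiplier = 10) {
  .checkInteractome(graph)
  if (igraph::ecount(graph) < 2L) stop("rewiring needs at least 2 edges")
  set.seed(as.integer(seed))
  nIter <- ceiling(nSwapMultiplier * igraph::ecount(graph))
  out <- igraph::rewire(graph, igraph::keeping_degseq(niter = nIter))
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L])))
  }
  if (identical(key(out), key(graph)))
    warning("rewiring left the graph unchanged (no legal swap found)")
  out
}

#' Modularity significance by rewiring null ensemble
#'
#' Compares the modularity of the best first-level partition of `graph`
#' against the same quantity computed on `nRandom` degree-preserving
#' rewired copies. The empirical p-value is
#' `(1 + #\{Q_null >= Q_obs\}) / (1 + nRandom)`.
#'
#' @param graph Undirected simple graph.
#' @param nRandom Number of rewired graphs (default 100).
#' @param seed Integer seed driving both the partitions and the rewirings.
#' @param nSwapMultiplier Passed to [degreePreservingRewire()].
#' @param nRestarts Passed to [louvainPartition()].
#' @return A [NullEnsembleSummary].
#' @export
modularityNullTest <- function(graph, nRandom = 100L, seed,
                               nSwapMultiplier = 10, nRestarts = 10L) {
  nRandom <- .assertCount(nRandom, "nRandom")
  if (nRandom < 1L) stop("nRandom must be >= 1")
  obs <- louvainPartition(graph, seed = deriveSeed(seed, 0L),
                          nRestarts = nRestarts)
  qNull <- vapply(seq_len(nRandom), function(i) {
    gr <- degreePreservingRewire(graph, seed = deriveSeed(seed, 2L * i),
                                 nSwapMultiplier = nSwapMultiplier)
    modularityQ(louvainPartition(gr, seed = deriveSeed(seed, 2L * i + 1L),
                                 nRestarts = nRestarts))
  }, numeric(1))
  new("NullEnsembleSummary",
      qObserved = modularityQ(obs), qNull = qNull, nRandom = nRandom,
      pEmpirical = empiricalP(sum(qNull >= modularityQ(obs)), nRandom))
}

#' k-core decomposition of a network
#'
#' Coreness by iterative peeling: for k = 1, 2, ... repeatedly delete all
#' nodes of degree < k; K(v) is the largest k for which v survives in the
#' k-core. High-K nodes form the network center.
#'
#' @param graph Undirected simple graph with named vertices.
#' @return A [CorenessMap].
#' @export
kcoreDecompose <- function(graph) {
  .checkInteractome(graph)
  k <- igraph::coreness(graph)
  new("CorenessMap", coreness = setNames(as.integer(k), igraph::V(graph)$name))
}

#' Sub-cluster one module by first-level modularity maximization
#'
#' Applies [louvainPartition()] to the subgraph induced by a module's
#' genes. Genes in singleton components become singleton sub-clusters. If
#' the induced subgraph has no edges at all, every gene becomes its own
#' sub-cluster (with a warning) and `q` is `NA`.
#'
#' @param graph The full network.
#' @param moduleGenes Character vector of genes, all present in `graph`.
#' @param seed Integer seed.
#' @param nRestarts Passed to [louvainPartition()].
#' @return A [ModulePartition] over `moduleGenes` (level 2).
#' @export
subclusterModule <- function(graph, moduleGenes, seed, nRestarts = 10L) {
  .checkInteractome(graph)
  miss <- setdiff(moduleGenes, igraph::V(graph)$name)
  if (length(miss) > 0L)
    stop("module gene(s) absent from graph, e.g. ", miss[1L])
  if (length(moduleGenes) == 0L) stop("empty module")
  sub <- igraph::induced_subgraph(graph, moduleGenes)
  if (igraph::ecount(sub) == 0L) {
    warning("induced subgraph has no edges; every gene is its own sub-cluster")
    assign <- setNames(seq_along(moduleGenes) - 1L, moduleGenes)
    return(new("ModulePartition", assignment = assign, q = NA_real_,
               level = 2L, seed = as.integer(seed)))
  }
  p <- louvainPartition(sub, seed = seed, nRestarts = nRestarts)
  initialize(p, level = 2L)
}

#' Write a partition as TSV plus a JSON provenance sidecar
#'
#' The TSV holds columns `gene`, `module_id`; the sidecar
#' (`<path>.json`) records Q, level, seed and node/edge counts of the
#' source graph when given.
#'
#' @param partition A [ModulePartition].
#' @param path Output TSV path.
#' @param graph Optional source graph, for node/edge counts in the sidecar.
#' @return `path`, invisibly.
#' @export
writePartition <- function(partition, path, graph = NULL) {
  a <- moduleAssignment(partition)
  df <- data.frame(gene = names(a), module_id = unname(a),
                   stringsAsFactors = FALSE)
  df <- df[order(df$module_id, df$gene), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(q = modularityQ(partition), level = partitionLevel(partition),
               seed = partition@seed, n_genes = length(a),
               n_modules = max(a) + 1L)
  if (!is.null(graph)) {
    meta$n_nodes <- igraph::vcount(graph)
    meta$n_edges <- igraph::ecount(graph)
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a coreness map as TSV (columns `gene`, `K`)
#'
#' @param corenessMap A [CorenessMap].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeCoreness <- function(corenessMap, path) {
  k <- geneCoreness(corenessMap)
  df <- data.frame(gene = names(k), K = unname(k), stringsAsFactors = FALSE)
  df <- df[order(-df$K, df$gene), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
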