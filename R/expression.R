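# Expression containers: functions accept either a plain genes x samples
# matrix or a SummarizedExperiment carrying one in its first assay.

.exprMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, 1L)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)) > 0L) stop("duplicate gene ids")
  if (anyDuplicated(colnames(x)) > 0L) stop("duplicate sample ids")
  x
}

#' Read an expression matrix (genes x samples TSV)
#'
#' First column holds gene symbols, remaining columns one sample each.
#' Rows mapping to the same gene (multiple probes) are averaged. Negative
#' values are rejected: the container models array intensities or FPKM.
#'
#' @param path Expression TSV path.
#' @param sampleAnnotationPath Optional TSV with a `sample` column plus
#'   arbitrary annotations (`tissue_label`, `subject`, `condition`,
#'   `pair_id`, ...); attached as `colData`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `expr`.
#' @export
readExpressionMatrix <- function(path, sampleAnnotationPath = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus samples")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("missing values in expression matrix")
  if (any(m < 0)) stop("negative expression values")
  if (anyDuplicated(genes) > 0L) {
    # multiple probes per gene: average signals
    m <- rowsum(m, group = genes) / as.vector(table(genes)[sort(unique(genes))])
    m <- m[match(unique(genes), rownames(m)), , drop = FALSE]
  } else {
    rownames(m) <- genes
  }
  cd <- NULL
  if (!is.null(sampleAnnotationPath)) {
    ann <- read.delim(sampleAnnotationPath, stringsAsFactors = FALSE)
    if (!"sample" %in% names(ann)) stop("sample annotation needs a 'sample' column")
    ann <- ann[match(colnames(m), ann$sample), , drop = FALSE]
    rownames(ann) <- colnames(m)
    cd <- S4Vectors::DataFrame(ann)
  }
  if (is.null(cd)) {
    SummarizedExperiment::SummarizedExperiment(assays = list(expr = m))
  } else {
    SummarizedExperiment::SummarizedExperiment(assays = list(expr = m),
                                               colData = cd)
  }
}

#' Write an expression matrix as TSV
#'
#' @param x Matrix or SummarizedExperiment.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  m <- .exprMatrix(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-score each gene's expression profile across samples
#'
#' Centers and scales every row to mean 0, sd 1 ("normalized across
#' sections"). Constant rows carry no relative-abundance information and
#' are dropped with a warning; the per-gene centers and scales are kept in
#' `rowData` so the transform can be inverted.
#'
#' @param x Matrix or SummarizedExperiment (non-negative values).
#' @return A SummarizedExperiment with assay `zscore` and `rowData` columns
#'   `gene_mean`, `gene_sd`.
#' @export
normalizePerGene <- function(x) {
  m <- .exprMatrix(x)
  if (ncol(m) < 2L) stop("need at least 2 samples per gene")
  sds <- apply(m, 1L, sd)
  drop <- sds == 0 | is.na(sds)
  if (all(drop)) stop("all gene rows are constant; nothing to normalize")
  if (any(drop)) {
    warning(sum(drop), " constant gene row(s) dropped before z-scoring")
    m <- m[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  mus <- rowMeans(m)
  z <- (m - mus) / sds
  SummarizedExperiment::SummarizedExperiment(
    assays = list(zscore = z),
    rowData = S4Vectors::DataFrame(gene_mean = mus, gene_sd = sds))
}

#' Two-way dichotomization of an expression matrix
#'
#' Hierarchically clusters the z-scored genes (distance 1 - Pearson
#' correlation) and the samples (Euclidean distance on the z-scored
#' columns), cuts both trees at two clusters, and fixes labels so that gene
#' group 1 is the group with the highest mean z-score, attained in sample
#' cluster T1. This mirrors the classic expression-heatmap reading: group 1
#' = genes preferentially expressed in the T1 regions, group 2 = genes
#' elevated in the complementary T2 regions.
#'
#' @param x Matrix or SummarizedExperiment with >= 4 genes and >= 4 samples.
#' @param linkage Agglomeration method (default `"average"`).
#' @return A [DichotomyResult].
#' @export
dichotomize <- function(x, linkage = "average") {
  m <- .exprMatrix(x)
  if (nrow(m) < 4L || ncol(m) < 4L)
    stop("dichotomization needs at least 4 genes and 4 samples")
  z <- SummarizedExperiment::assay(normalizePerGene(m), 1L)
  if (nrow(z) < 4L) stop("too few variable genes after dropping constants")
  dg <- as.dist(1 - cor(t(z)))
  if (any(is.na(dg))) stop("degenerate matrix: undefined gene correlations")
  gTree <- hclust(dg, method = linkage)
  gCut <- cutree(gTree, k = 2L)
  sTree <- hclust(dist(t(z)), method = linkage)
  sCut <- cutree(sTree, k = 2L)
  # label convention: the (gene group, sample cluster) cell with the highest
  # mean z-score defines (group 1, T1)
  cellMean <- sapply(1:2, function(s) sapply(1:2, function(g)
    mean(z[gCut == g, sCut == s, drop = FALSE])))
  top <- which(cellMean == max(cellMean), arr.ind = TRUE)[1L, ]
  geneGroup <- ifelse(gCut == top[["row"]], 1L, 2L)
  sampleCluster <- ifelse(sCut == top[["col"]], "T1", "T2")
  new("DichotomyResult",
      geneGroup = setNames(as.integer(geneGroup), rownames(z)),
      sampleCluster = setNames(sampleCluster, colnames(z)),
      linkageMethod = linkage, distanceMetric = "cor/euclidean")
}

#' Tissue-specificity index tau
#'
#' For a gene's non-negative expression over N tissues,
#' tau = sum_i (1 - x_i / max_j x_j) / (N - 1): 0 for uniform expression,
#' 1 when expression is confined to a single tissue. Scale-invariant.
#'
#' @param x Non-negative numeric vector (one gene over >= 2 samples), or a
#'   matrix / SummarizedExperiment for a per-gene vector of tau values.
#' @return tau in [0, 1]; `NA` (with a warning) for an all-zero profile.
#' @export
#' @examples
#' tauIndex(c(1, 0.5, 0))  # 0.75
tauIndex <- function(x) {
  if (is.matrix(x) || is(x, "SummarizedExperiment")) {
    m <- .exprMatrix(x)
    return(apply(m, 1L, tauIndex))
  }
  if (length(x) < 2L) stop("tau needs at least 2 samples")
  if (any(is.na(x)) || any(x < 0)) stop("tau is defined for non-negative values")
  mx <- max(x)
  if (mx == 0) {
    warning("all-zero expression profile: tau undefined")
    return(NA_real_)
  }
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Expression breadth at transcriptome-wide activity cutoffs
#'
#' For each quantile threshold q, the activity cutoff is the q-quantile of
#' the pooled value distribution across all genes and samples (linear
#' interpolation); a gene's breadth is the number of samples in which its
#' value reaches the cutoff. Values below the cutoff are deemed inactive.
#'
#' @param x Matrix or SummarizedExperiment.
#' @param quantileThresholds Fractions in (0, 1); default `c(0.15, 0.25,
#'   0.50)`.
#' @return Integer matrix genes x thresholds (columns `q0.15`, ...), with
#'   the cutoffs in `attr(, "cutoffs")`.
#' @export
expressionBreadth <- function(x, quantileThresholds = c(0.15, 0.25, 0.50)) {
  m <- .exprMatrix(x)
  q <- quantileThresholds
  if (any(q <= 0) || any(q >= 1)) stop("thresholds must lie in (0, 1)")
  cuts <- quantile(as.vector(m), q, names = FALSE)  # pooled distribution
  b <- vapply(cuts, function(ct) as.integer(rowSums(m >= ct)),
              integer(nrow(m)))
  if (nrow(m) == 1L) b <- matrix(b, nrow = 1L)
  dimnames(b) <- list(rownames(m), sprintf("q%.2f", q))
  attr(b, "cutoffs") <- setNames(cuts, sprintf("q%.2f", q))
  b
}

#' Compare a gene group's expression to a sampled transcriptome background
#'
#' Per sample, a two-sided Wilcoxon rank-sum test of the group genes'
#' values against the values of `backgroundSize` randomly sampled non-group
#' genes (one background draw, reused across samples so per-sample results
#' are comparable).
#'
#' @param x Matrix or SummarizedExperiment.
#' @param group Character vector of group genes (subset of the matrix).
#' @param backgroundSize Number of background genes to sample (capped at
#'   the number available).
#' @param seed Integer seed for the background draw.
#' @return data.frame `sample`, `statistic`, `p`, `direction` (+1 if the
#'   group median exceeds the background median, else -1).
#' @export
groupVsBackground <- function(x, group, backgroundSize = 1000L, seed = 1L) {
  m <- .exprMatrix(x)
  group <- intersect(group, rownames(m))
  if (length(group) == 0L) stop("no group gene present in the matrix")
  rest <- setdiff(rownames(m), group)
  if (length(rest) == 0L) stop("empty background: group covers all genes")
  set.seed(as.integer(seed))
  bg <- if (length(rest) > backgroundSize)
    sample(rest, backgroundSize) else rest
  res <- lapply(colnames(m), function(s) {
    gv <- m[group, s]
    bv <- m[bg, s]
    wt <- suppressWarnings(wilcox.test(gv, bv))
    data.frame(sample = s, statistic = unname(wt$statistic), p = wt$p.value,
               direction = if (median(gv) >= median(bv)) 1L else -1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Co-expression quality check of an interaction network
#'
#' Interacting proteins tend to be co-expressed; this contrasts the Pearson
#' correlation (across samples) of interacting gene pairs with that of
#' random non-adjacent pairs, via a two-sided Wilcoxon rank-sum test.
#' Pairs involving a constant gene are excluded.
#'
#' @param graph Undirected network with named vertices.
#' @param x Matrix or SummarizedExperiment.
#' @param nRandomPairs Number of random non-adjacent pairs (default 1000).
#' @param seed Integer seed.
#' @return List: `interacting_r`, `random_r`, `p`,
#'   `median_interacting`, `median_random`, `n_pairs_used`.
#' @export
coexpressionQC <- function(graph, x, nRandomPairs = 1000L, seed = 1L) {
  .checkInteractome(graph)
  m <- .exprMatrix(x)
  ok <- rownames(m)[apply(m, 1L, sd) > 0]
  dropped <- setdiff(rownames(m), ok)
  if (length(dropped) > 0L)
    message(length(dropped), " constant gene(s) excluded from co-expression QC")
  el <- igraph::as_edgelist(graph)
  el <- el[el[, 1L] %in% ok & el[, 2L] %in% ok, , drop = FALSE]
  if (nrow(el) == 0L) stop("no usable interacting pair with expression data")
  rInt <- vapply(seq_len(nrow(el)),
                 function(i) cor(m[el[i, 1L], ], m[el[i, 2L], ]), numeric(1))
  set.seed(as.integer(seed))
  adj <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  rRnd <- numeric(0)
  guard <- 0L
  while (length(rRnd) < nRandomPairs && guard < 50L) {
    a <- sample(ok, nRandomPairs, replace = TRUE)
    b <- sample(ok, nRandomPairs, replace = TRUE)
    keep <- a != b & !(paste(pmin(a, b), pmax(a, b)) %in% adj)
    idx <- which(keep)[seq_len(min(sum(keep), nRandomPairs - length(rRnd)))]
    rRnd <- c(rRnd, vapply(idx, function(i) cor(m[a[i], ], m[b[i], ]),
                           numeric(1)))
    guard <- guard + 1L
  }
  wt <- suppressWarnings(wilcox.test(rInt, rRnd))
  list(interacting_r = rInt, random_r = rRnd, p = wt$p.value,
       median_interacting = median(rInt), median_random = median(rRnd),
       n_pairs_used = nrow(el))
}

#' Call genes with extreme expression changes in matched case-control pairs
#'
#' Per pair, genes where both case and control fall below `minExpr` are
#' excluded; for the rest the fold change is `(case + eps) / (control +
#' eps)`. A gene is up-extreme in a pair iff its fold change exceeds both
#' `fcMin` and the `upperQ` quantile of that pair's transcriptome-wide
#' fold-change distribution; down-extreme analogously with `1/fcMin` and
#' `lowerQ`. A gene is an extreme-DE call if extreme in at least one pair.
#'
#' @param caseExpr,controlExpr Genes x pairs matrices (or
#'   SummarizedExperiments) with identical dimnames; column j of each is
#'   the j-th matched pair.
#' @param fcMin Minimum fold change (> 1; default 2).
#' @param upperQ,lowerQ Transcriptome-wide quantile bounds (defaults 0.975
#'   / 0.025).
#' @param minExpr Low-expression exclusion cutoff (default 1, FPKM-like).
#' @param eps Pseudo-count stabilizing ratios at low control expression
#'   (default 0.01).
#' @return Long data.frame `gene`, `pair_id`, `fold_change`, `up_extreme`,
#'   `down_extreme`; genes excluded in a pair are absent for that pair.
#' @seealso [anyExtremeGenes()]
#' @export
extremeDECall <- function(caseExpr, controlExpr, fcMin = 2, upperQ = 0.975,
                          lowerQ = 0.025, minExpr = 1, eps = 0.01) {
  ca <- .exprMatrix(caseExpr)
  co <- .exprMatrix(controlExpr)
  if (!identical(dim(ca), dim(co)) || !identical(rownames(ca), rownames(co)))
    stop("case and control matrices must be index-paired (same genes, same pair count)")
  if (fcMin <= 1) stop("fcMin must exceed 1")
  if (!(lowerQ > 0 && lowerQ < upperQ && upperQ < 1))
    stop("need 0 < lowerQ < upperQ < 1")
  out <- lapply(seq_len(ncol(ca)), function(j) {
    keep <- ca[, j] >= minExpr | co[, j] >= minExpr
    if (!any(keep)) return(NULL)
    fc <- (ca[keep, j] + eps) / (co[keep, j] + eps)
    qU <- quantile(fc, upperQ, names = FALSE)
    qL <- quantile(fc, lowerQ, names = FALSE)
    data.frame(gene = rownames(ca)[keep], pair_id = j,
               fold_change = unname(fc),
               up_extreme = unname(fc > fcMin & fc > qU),
               down_extreme = unname(fc < 1 / fcMin & fc < qL),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no gene passed the expression filter in any pair")
  rownames(res) <- NULL
  res
}

#' Genes flagged extreme in at least one case-control pair
#'
#' @param de Output of [extremeDECall()].
#' @return Character vector of genes with `up_extreme` or `down_extreme`
#'   in any pair.
#' @export
anyExtremeGenes <- function(de) {
  sort(unique(de$gene[de$up_extreme | de$down_extreme]))
}

#' Module enrichment for differentially expressed genes
#'
#' Hypergeometric upper-tail test of the overlap between extreme-DE genes
#' and a module, over the network universe.
#'
#' @param deGenes Character vector of DE genes (e.g. [anyExtremeGenes()]).
#' @param module Character vector of module genes (within `universe`).
#' @param universe Character vector (network node set).
#' @return One-row data.frame `k`, `n`, `K_set`, `N_u`, `p`.
#' @export
deModuleEnrichment <- function(deGenes, module, universe) {
  universe <- unique(universe)
  if (!all(module %in% universe)) stop("module must lie within the universe")
  deU <- intersect(unique(deGenes), universe)
  k <- length(intersect(deU, module))
  data.frame(k = k, n = length(module), K_set = length(deU),
             N_u = length(universe),
             p = hypergeomUpperTail(k, length(module), length(deU),
                                    length(universe)))
}
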