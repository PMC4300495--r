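#' Hypergeometric upper-tail (enrichment) p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `nDraws` genes from a
#' universe of `NUniverse` genes of which `KMarked` are marked, what is the
#' chance of seeing at least `k` marked genes? Computed in log space via the
#' exact distribution function, so tiny tail probabilities are stable.
#'
#' @param k Observed overlap count.
#' @param nDraws Number of genes drawn (e.g. module size).
#' @param KMarked Number of marked genes in the universe (e.g. gene-set size).
#' @param NUniverse Universe size (e.g. network node count).
#' @return The upper-tail p-value (1 when `k` = 0).
#' @export
#' @examples
#' hypergeomUpperTail(14, 16, 38, 119)  # 1.2e-6
hypergeomUpperTail <- function(k, nDraws, KMarked, NUniverse) {
  k <- .assertCount(k, "k")
  nDraws <- .assertCount(nDraws, "nDraws")
  KMarked <- .assertCount(KMarked, "KMarked")
  NUniverse <- .assertCount(NUniverse, "NUniverse")
  if (k > nDraws || nDraws > NUniverse || KMarked > NUniverse)
    stop("impossible counts: need k <= nDraws <= NUniverse and KMarked <= NUniverse")
  if (k == 0L) return(1)
  phyper(k - 1L, KMarked, NUniverse - KMarked, nDraws, lower.tail = FALSE)
}

#' Hypergeometric lower-tail (depletion) p-value
#'
#' P(X <= k); the depletion counterpart of [hypergeomUpperTail()].
#'
#' @inheritParams hypergeomUpperTail
#' @return The lower-tail p-value.
#' @export
hypergeomLowerTail <- function(k, nDraws, KMarked, NUniverse) {
  k <- .assertCount(k, "k")
  if (k > nDraws || nDraws > NUniverse || KMarked > NUniverse)
    stop("impossible counts: need k <= nDraws <= NUniverse and KMarked <= NUniverse")
  phyper(k, KMarked, NUniverse - KMarked, nDraws, lower.tail = TRUE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test of association; the two-sided p-value sums the
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The exact p-value.
#' @export
#' @examples
#' fisher2x2(matrix(c(25, 94, 95, 1650), 2, byrow = TRUE))  # 3.28e-8
fisher2x2 <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("'tab' must be a 2x2 matrix")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("'tab' must hold non-negative integer counts")
  if (all(rowSums(tab) == 0) || all(colSums(tab) == 0))
    stop("at least one margin must be positive")
  # the conditional sum can exceed 1 by a few ulps
  min(1, fisher.test(tab, alternative = alternative)$p.value)
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1; input
#' order is preserved.
#'
#' @param pValues Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same length and order.
#' @export
bhAdjust <- function(pValues) {
  .assertProb(pValues, "pValues")
  p.adjust(pValues, method = "BH")
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member symbols, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (duplicates within a set removed).
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line (need name, description, genes)")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  sets
}

#' Read a gene set given one symbol per line
#'
#' @param path File path.
#' @return Character vector of unique symbols.
#' @export
readGeneList <- function(path) {
  g <- trimws(readLines(path, warn = FALSE))
  g <- unique(g[nzchar(g)])
  if (length(g) == 0L) stop("empty gene list: ", path)
  g
}

#' Read a gene annotation table
#'
#' Header TSV with mandatory columns `gene`, `cds_length`, `gc_content`;
#' any further columns are kept (boolean-like columns are coerced to
#' logical membership flags).
#'
#' @param path TSV path.
#' @return A data.frame, one row per gene.
#' @export
readGeneAnnotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "cds_length", "gc_content")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  validateAnnotation(df)
}

#' Validate a gene annotation table's invariants
#'
#' One row per gene, positive CDS lengths, GC content in [0, 1].
#'
#' @param annotation A data.frame with `gene`, `cds_length`, `gc_content`.
#' @return The (possibly flag-coerced) data.frame, invisibly usable.
#' @export
validateAnnotation <- function(annotation) {
  if (anyDuplicated(annotation$gene) > 0L)
    stop("duplicated gene rows in annotation")
  if (any(annotation$cds_length <= 0)) stop("cds_length must be positive")
  .assertProb(annotation$gc_content, "gc_content")
  extra <- setdiff(names(annotation), c("gene", "cds_length", "gc_content"))
  for (cl in extra) {
    v <- annotation[[cl]]
    if (is.character(v) && all(toupper(v) %in% c("TRUE", "FALSE", "0", "1")))
      annotation[[cl]] <- as.logical(v) | v %in% "1"
  }
  annotation
}

# One trim step: drop the extreme decile of the candidate values on the
# side where the candidate distribution overshoots the target median.
.trimDecile <- function(candVals, targetVals) {
  if (median(candVals) > median(targetVals)) {
    candVals <= quantile(candVals, 0.9, names = FALSE)
  } else {
    candVals >= quantile(candVals, 0.1, names = FALSE)
  }
}

#' Build a covariate-matched background gene pool
#'
#' Constructs, per covariate, a candidate pool of non-target genes whose
#' covariate values fall inside the target set's [2.5, 97.5] percentile
#' range, then iteratively trims the extreme decile on the imbalanced side
#' until a two-sample Wilcoxon rank test against the target exceeds
#' `balanceThreshold`. The final pool is the intersection of the
#' per-covariate pools (target genes excluded); if intersecting breaks a
#' covariate's balance the trimming resumes on the intersection.
#'
#' @param target Character vector of target genes (e.g. a curated disease
#'   list); all must be annotated.
#' @param annotation Gene annotation data.frame ([readGeneAnnotation()]).
#' @param covariates Covariate column names to balance (default CDS length
#'   and GC content).
#' @param balanceThreshold Required rank-test p-value (default 0.05).
#' @param seed Integer seed (reserved for future subsampling; the trimming
#'   itself is deterministic).
#' @return A [MatchedBackground].
#' @export
buildMatchedBackground <- function(target, annotation,
                                   covariates = c("cds_length", "gc_content"),
                                   balanceThreshold = 0.05, seed = 1L) {
  miss <- setdiff(covariates, names(annotation))
  if (length(miss) > 0L)
    stop("covariate(s) absent from annotation: ", paste(miss, collapse = ", "))
  unann <- setdiff(target, annotation$gene)
  if (length(unann) > 0L)
    stop("target gene(s) missing from annotation, e.g. ", unann[1L])
  rownames(annotation) <- annotation$gene
  targetVals <- lapply(covariates, function(cv) annotation[target, cv])
  names(targetVals) <- covariates
  candidates <- setdiff(annotation$gene, target)

  balanceP <- function(genes, cv)
    suppressWarnings(wilcox.test(annotation[genes, cv], targetVals[[cv]])$p.value)

  poolFor <- function(genes, cv) {
    rng <- quantile(targetVals[[cv]], c(0.025, 0.975), names = FALSE)
    vals <- annotation[genes, cv]
    keep <- genes[vals >= rng[1L] & vals <= rng[2L]]
    for (it in seq_len(50L)) {
      if (length(keep) < length(target))
        stop("matched pool for '", cv, "' shrank below the target size; ",
             "relax balanceThreshold or drop the covariate")
      if (balanceP(keep, cv) > balanceThreshold) return(keep)
      keep <- keep[.trimDecile(annotation[keep, cv], targetVals[[cv]])]
    }
    stop("could not balance covariate '", cv, "' within 50 trims; ",
         "relax balanceThreshold")
  }

  pools <- lapply(covariates, function(cv) poolFor(candidates, cv))
  pool <- Reduce(intersect, pools)
  # intersecting per-covariate pools can unbalance a covariate: re-trim on
  # the intersection until every covariate passes
  for (round in seq_len(20L)) {
    ps <- vapply(covariates, function(cv) balanceP(pool, cv), numeric(1))
    if (all(ps > balanceThreshold)) break
    cv <- covariates[which.min(ps)]
    if (length(pool) < length(target))
      stop("matched pool shrank below the target size; relax balanceThreshold")
    pool <- poolFor(pool, cv)
  }
  if (length(pool) < length(target))
    stop("matched pool smaller than the target set; relax balanceThreshold")
  ps <- vapply(covariates, function(cv) balanceP(pool, cv), numeric(1))
  if (any(ps <= balanceThreshold))
    stop("could not jointly balance all covariates; relax balanceThreshold")
  new("MatchedBackground", genes = pool, target = target,
      balance = setNames(ps, covariates), covariates = covariates,
      threshold = balanceThreshold)
}

#' Matched-sampling permutation test of module overlap
#'
#' Draws `nPerm` pseudo-target sets of size `|target|` from the matched
#' background pool and compares each draw's overlap with the module to the
#' observed overlap `|target` \eqn{\cap} `module|`. The empirical p-value is
#' `(1 + #\{overlap_perm >= overlap_obs\}) / (1 + nPerm)`.
#'
#' @param module Character vector: the module's genes.
#' @param target Character vector: the target gene set.
#' @param pool A [MatchedBackground] built for `target`.
#' @param nPerm Number of permutations.
#' @param seed Integer seed.
#' @return List with `observed`, `permuted` (integer vector), `p`.
#' @export
matchedPermutationTest <- function(module, target, pool, nPerm, seed) {
  nPerm <- .assertCount(nPerm, "nPerm")
  if (nPerm < 1L) stop("nPerm must be >= 1")
  genes <- poolGenes(pool)
  if (length(genes) < length(target))
    stop("pool smaller than the target set")
  obs <- length(intersect(target, module))
  inModule <- genes %in% module
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(nPerm), function(i)
    sum(inModule[sample.int(length(genes), length(target))]), integer(1))
  list(observed = obs, permuted = perm,
       p = empiricalP(sum(perm >= obs), nPerm))
}

#' Scan all modules against all gene sets (hypergeometric + BH)
#'
#' For every module with more than `minModuleSize - 1` genes and every gene
#' set, computes the hypergeometric upper-tail p-value of the overlap with
#' the network node set (or a supplied universe), then applies BH within
#' the whole scan.
#'
#' @param partition A [ModulePartition].
#' @param sets Named list of character vectors (e.g. from [readGmt()]).
#' @param universe Character vector; defaults to the partition's genes
#'   (the network).
#' @param minModuleSize Smallest module size tested (default 6, i.e.
#'   "more than five genes").
#' @return data.frame with columns `module_id`, `set_name`, `k`, `n`,
#'   `K_set`, `N_u`, `p`, `fdr`, sorted by `fdr`.
#' @export
moduleSetScan <- function(partition, sets, universe = NULL,
                          minModuleSize = 6L) {
  if (length(sets) == 0L) stop("empty gene-set list")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("gene sets must be named")
  assign <- moduleAssignment(partition)
  if (is.null(universe)) universe <- names(assign)
  universe <- unique(universe)
  N <- length(universe)
  assign <- assign[names(assign) %in% universe]
  sizes <- table(assign)
  ids <- as.integer(names(sizes))[sizes >= minModuleSize]
  if (length(ids) == 0L)
    return(data.frame(module_id = integer(), set_name = character(),
                      k = integer(), n = integer(), K_set = integer(),
                      N_u = integer(), p = numeric(), fdr = numeric()))
  setsU <- lapply(sets, function(s) intersect(unique(s), universe))
  rows <- do.call(rbind, lapply(ids, function(id) {
    mg <- names(assign)[assign == id]
    do.call(rbind, lapply(names(setsU), function(sn) {
      k <- length(intersect(mg, setsU[[sn]]))
      data.frame(module_id = id, set_name = sn, k = k, n = length(mg),
                 K_set = length(setsU[[sn]]), N_u = N,
                 p = hypergeomUpperTail(k, length(mg),
                                        length(setsU[[sn]]), N),
                 stringsAsFactors = FALSE)
    }))
  }))
  rows$fdr <- bhAdjust(rows$p)
  rows[order(rows$fdr, rows$p, rows$module_id), , drop = FALSE]
}

#' Enriched-module counts across a gradient of size thresholds
#'
#' Computes the module-set scan once at the smallest threshold (a single BH
#' family, so counts are comparable and monotone across thresholds), then
#' for each threshold counts the modules of at least that size with at
#' least one set at `fdr < fdrCut`.
#'
#' @param partition A [ModulePartition].
#' @param sets Named list of gene sets.
#' @param universe Universe genes (default: network).
#' @param thresholds Increasing integer vector of minimum module sizes
#'   (default 1:20).
#' @param fdrCut FDR cutoff (default 0.1).
#' @return data.frame `threshold`, `n_enriched_modules`, `gradient` (first
#'   difference; `NA` for the first row).
#' @export
sizeThresholdScan <- function(partition, sets, universe = NULL,
                              thresholds = 1:20, fdrCut = 0.1) {
  if (length(thresholds) == 0L || is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be non-empty and strictly increasing")
  scan <- moduleSetScan(partition, sets, universe,
                        minModuleSize = min(thresholds))
  hit <- scan[scan$fdr < fdrCut, , drop = FALSE]
  hitSize <- tapply(hit$n, hit$module_id, `[`, 1L)
  counts <- vapply(thresholds, function(t) sum(hitSize >= t), integer(1))
  data.frame(threshold = as.integer(thresholds),
             n_enriched_modules = counts,
             gradient = c(NA_integer_, diff(counts)))
}
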