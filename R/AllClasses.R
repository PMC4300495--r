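#' @import methods
#' @importFrom stats median mad quantile sd cor dist as.dist hclust cutree
#'   cor.test fisher.test p.adjust phyper wilcox.test lm residuals optim qt
#'   rbinom rnorm rbeta rlnorm rpois runif setNames
#' @importFrom utils read.delim write.table head packageVersion
NULL

#' Gene-to-module assignment with its modularity score
#'
#' A partition of an interaction network into topological modules, as
#' produced by first-level modularity maximization ([louvainPartition()]) or
#' sub-clustering ([subclusterModule()]). Module ids are contiguous integers
#' starting at 0; the `q` slot stores the Newman--Girvan modularity of the
#' assignment on the graph it was computed from.
#'
#' @slot assignment Named integer vector: gene symbol -> module id (0-based,
#'   contiguous).
#' @slot q Modularity score Q of the assignment (dimensionless, in [-1, 1]).
#'   `NA` when the source graph had no edges.
#' @slot level Which pass of the multilevel heuristic produced the partition
#'   (1 = first level).
#' @slot seed Integer seed the partition was computed under (`NA` if none).
#'
#' @seealso [louvainPartition()], [moduleAssignment()], [modularityScore()]
#' @export
setClass("ModulePartition",
  representation(
    assignment = "integer",
    q = "numeric",
    level = "integer",
    seed = "integer"
  ),
  prototype(q = NA_real_, level = 1L, seed = NA_integer_)
)

setValidity("ModulePartition", function(object) {
  a <- object@assignment
  if (length(a) == 0L) return("assignment is empty")
  if (is.null(names(a)) || anyNA(names(a)) || any(names(a) == ""))
    return("assignment must be named by gene symbol")
  if (anyDuplicated(names(a)) > 0L)
    return("duplicate gene symbols in assignment")
  ids <- sort(unique(a))
  if (!identical(ids, seq(0L, max(a))))
    return("module ids must be contiguous integers starting at 0")
  if (length(object@q) != 1L) return("q must be a single number")
  if (!is.na(object@q) && (object@q < -1 || object@q > 1))
    return("q outside [-1, 1]")
  TRUE
})

#' @describeIn ModulePartition Gene -> module id lookup (named integer).
#' @param x,object A `ModulePartition`.
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))

#' @rdname ModulePartition
#' @export
setMethod("moduleAssignment", "ModulePartition", function(x) x@assignment)

#' @describeIn ModulePartition Modularity Q of the partition.
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))

#' @rdname ModulePartition
#' @export
setMethod("modularityQ", "ModulePartition", function(x) x@q)

#' @describeIn ModulePartition Hierarchy level that produced the partition.
#' @export
setGeneric("partitionLevel", function(x) standardGeneric("partitionLevel"))

#' @rdname ModulePartition
#' @export
setMethod("partitionLevel", "ModulePartition", function(x) x@level)

#' @describeIn ModulePartition Module sizes, indexed by module id.
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname ModulePartition
#' @export
setMethod("moduleSizes", "ModulePartition", function(x) {
  tab <- table(x@assignment)
  setNames(as.integer(tab), names(tab))
})

#' @describeIn ModulePartition Genes belonging to one module.
#' @param id Module id (0-based).
#' @export
setGeneric("moduleGenes", function(x, id) standardGeneric("moduleGenes"))

#' @rdname ModulePartition
#' @export
setMethod("moduleGenes", "ModulePartition", function(x, id) {
  names(x@assignment)[x@assignment == id]
})

setMethod("show", "ModulePartition", function(object) {
  cat(sprintf(
    "ModulePartition: %d genes in %d modules (level %d)\n  Q = %.4f%s\n",
    length(object@assignment), max(object@assignment) + 1L, object@level,
    object@q, if (is.na(object@seed)) "" else sprintf(", seed = %d", object@seed)
  ))
  sz <- sort(moduleSizes(object), decreasing = TRUE)
  cat("  largest modules:", paste(head(sz, 5L), collapse = ", "), "\n")
})

#' Per-gene coreness from k-core decomposition
#'
#' Coreness K of a gene is the largest k such that the gene survives in the
#' k-core (the maximal subgraph of minimum degree >= k). High K marks the
#' network center, K = 1 the periphery.
#'
#' @slot coreness Named integer vector: gene symbol -> K (>= 1 on a graph
#'   without isolated nodes).
#'
#' @seealso [kcoreDecompose()]
#' @export
setClass("CorenessMap", representation(coreness = "integer"))

setValidity("CorenessMap", function(object) {
  k <- object@coreness
  if (length(k) == 0L) return("coreness is empty")
  if (is.null(names(k)) || anyDuplicated(names(k)) > 0L)
    return("coreness must be uniquely named by gene")
  if (any(k < 0L)) return("negative coreness")
  TRUE
})

#' @describeIn CorenessMap Named integer vector of K values.
#' @param x,object A `CorenessMap`.
#' @export
setGeneric("geneCoreness", function(x) standardGeneric("geneCoreness"))

#' @rdname CorenessMap
#' @export
setMethod("geneCoreness", "CorenessMap", function(x) x@coreness)

setMethod("show", "CorenessMap", function(object) {
  k <- object@coreness
  cat(sprintf("CorenessMap: %d genes, K in [%d, %d]\n",
              length(k), min(k), max(k)))
})

#' Modularity significance against degree-preserving rewiring nulls
#'
#' Summary of a null-ensemble test: the observed modularity of the real
#' network compared with the modularities of degree-preserving rewired
#' copies. The empirical p-value uses the (1 + exceedances) / (1 + n)
#' convention and is therefore never 0.
#'
#' @slot qObserved Modularity of the best first-level partition of the
#'   observed graph.
#' @slot qNull Modularities of the rewired graphs (length `nRandom`).
#' @slot nRandom Number of rewired graphs.
#' @slot pEmpirical Empirical p-value in (0, 1].
#'
#' @seealso [modularityNullTest()]
#' @export
setClass("NullEnsembleSummary",
  representation(
    qObserved = "numeric",
    qNull = "numeric",
    nRandom = "integer",
    pEmpirical = "numeric"
  )
)

setValidity("NullEnsembleSummary", function(object) {
  if (length(object@qNull) != object@nRandom)
    return("length(qNull) != nRandom")
  if (object@pEmpirical <= 0 || object@pEmpirical > 1)
    return("pEmpirical outside (0, 1]")
  TRUE
})

#' @describeIn NullEnsembleSummary Empirical p-value of the observed Q.
#' @param x,object A `NullEnsembleSummary`.
#' @export
setGeneric("pEmpirical", function(x) standardGeneric("pEmpirical"))

#' @rdname NullEnsembleSummary
#' @export
setMethod("pEmpirical", "NullEnsembleSummary", function(x) x@pEmpirical)

#' @describeIn NullEnsembleSummary Null modularity vector.
#' @export
setGeneric("nullModularities", function(x) standardGeneric("nullModularities"))

#' @rdname NullEnsembleSummary
#' @export
setMethod("nullModularities", "NullEnsembleSummary", function(x) x@qNull)

#' @describeIn NullEnsembleSummary Observed modularity.
#' @export
setGeneric("observedModularity", function(x) standardGeneric("observedModularity"))

#' @rdname NullEnsembleSummary
#' @export
setMethod("observedModularity", "NullEnsembleSummary", function(x) x@qObserved)

setMethod("show", "NullEnsembleSummary", function(object) {
  cat(sprintf(
    "NullEnsembleSummary: Q_obs = %.4f vs %d rewired nulls (max %.4f)\n  empirical P = %.4g\n",
    object@qObserved, object@nRandom, max(object@qNull), object@pEmpirical
  ))
})

#' Covariate-matched background gene pool
#'
#' A pool of control genes whose covariate distributions (typically CDS
#' length and GC content) are statistically indistinguishable from a target
#' gene set, used in place of the whole genome when permutation-testing
#' enrichment so that covariate confounding cannot masquerade as signal.
#'
#' @slot genes Pool gene symbols; always disjoint from the target set.
#' @slot target The target gene set the pool was matched to.
#' @slot balance Named numeric: per-covariate two-sample rank-test p-value of
#'   pool vs target; all exceed `threshold`.
#' @slot covariates Covariate names used for matching.
#' @slot threshold Balance threshold the pool satisfies.
#'
#' @seealso [buildMatchedBackground()], [matchedPermutationTest()]
#' @export
setClass("MatchedBackground",
  representation(
    genes = "character",
    target = "character",
    balance = "numeric",
    covariates = "character",
    threshold = "numeric"
  )
)

setValidity("MatchedBackground", function(object) {
  if (length(object@genes) == 0L) return("empty pool")
  if (length(intersect(object@genes, object@target)) > 0L)
    return("pool overlaps the target set")
  if (any(object@balance <= object@threshold))
    return("a covariate balance p-value does not exceed the threshold")
  if (!identical(sort(names(object@balance)), sort(object@covariates)))
    return("balance p-values must be named by covariate")
  TRUE
})

#' @describeIn MatchedBackground Pool gene symbols.
#' @param x,object A `MatchedBackground`.
#' @export
setGeneric("poolGenes", function(x) standardGeneric("poolGenes"))

#' @rdname MatchedBackground
#' @export
setMethod("poolGenes", "MatchedBackground", function(x) x@genes)

#' @describeIn MatchedBackground Per-covariate balance p-values.
#' @export
setGeneric("balancePValues", function(x) standardGeneric("balancePValues"))

#' @rdname MatchedBackground
#' @export
setMethod("balancePValues", "MatchedBackground", function(x) x@balance)

setMethod("show", "MatchedBackground", function(object) {
  cat(sprintf(
    "MatchedBackground: %d pool genes matched to %d targets on %s\n  balance p: %s (all > %.3g)\n",
    length(object@genes), length(object@target),
    paste(object@covariates, collapse = ", "),
    paste(sprintf("%s=%.3f", names(object@balance), object@balance),
          collapse = ", "),
    object@threshold
  ))
})

#' Two-way dichotomy of an expression matrix
#'
#' Result of hierarchically clustering genes and samples of a normalized
#' expression matrix and cutting both trees into two groups. By convention
#' gene group 1 is the group with the higher mean expression in sample
#' cluster T1.
#'
#' @slot geneGroup Named integer (1 or 2) per gene.
#' @slot sampleCluster Named character ("T1" or "T2") per sample.
#' @slot linkageMethod Agglomeration method used for both trees.
#' @slot distanceMetric Distances used, "cor" (1 - Pearson, genes) /
#'   "euclidean" (samples).
#'
#' @seealso [dichotomize()]
#' @export
setClass("DichotomyResult",
  representation(
    geneGroup = "integer",
    sampleCluster = "character",
    linkageMethod = "character",
    distanceMetric = "character"
  )
)

setValidity("DichotomyResult", function(object) {
  if (!all(object@geneGroup %in% c(1L, 2L)))
    return("gene groups must be 1 or 2")
  if (length(unique(object@geneGroup)) != 2L)
    return("both gene groups must be non-empty")
  if (!all(object@sampleCluster %in% c("T1", "T2")))
    return("sample clusters must be T1 or T2")
  if (length(unique(object@sampleCluster)) != 2L)
    return("both sample clusters must be non-empty")
  TRUE
})

#' @describeIn DichotomyResult Named gene-group vector (1/2).
#' @param x,object A `DichotomyResult`.
#' @export
setGeneric("geneGroups", function(x) standardGeneric("geneGroups"))

#' @rdname DichotomyResult
#' @export
setMethod("geneGroups", "DichotomyResult", function(x) x@geneGroup)

#' @describeIn DichotomyResult Named sample-cluster vector (T1/T2).
#' @export
setGeneric("sampleClusters", function(x) standardGeneric("sampleClusters"))

#' @rdname DichotomyResult
#' @export
setMethod("sampleClusters", "DichotomyResult", function(x) x@sampleCluster)

setMethod("show", "DichotomyResult", function(object) {
  cat(sprintf(
    "DichotomyResult: genes %d/%d (group 1/2), samples %d/%d (T1/T2)\n  %s linkage, %s distance\n",
    sum(object@geneGroup == 1L), sum(object@geneGroup == 2L),
    sum(object@sampleCluster == "T1"), sum(object@sampleCluster == "T2"),
    object@linkageMethod, object@distanceMetric
  ))
})
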