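#' Read a variant table
#'
#' Header TSV with columns `variant_id`, `gene`, `consequence`
#' (`nonsynonymous` / `silent` / `other`), `case_alt`, `case_an`, optional
#' `control_alt`, `control_an`, optional `ref_af` (empty/NA = absent from
#' the reference panel, i.e. "rare") and `ref_an`; any further columns
#' (conservation scores etc.) are carried through untouched.
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
readVariantTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", "", "."))
  validateVariantTable(df)
}

#' Validate a variant table's invariants
#'
#' @param variants A data.frame with the columns of [readVariantTable()].
#' @return The data.frame, unchanged, on success.
#' @export
validateVariantTable <- function(variants) {
  need <- c("variant_id", "gene", "consequence", "case_alt", "case_an")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0L)
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$variant_id) > 0L)
    stop("duplicated variant_id values")
  with(variants, {
    if (any(case_alt < 0 | case_alt > case_an))
      stop("need 0 <= case_alt <= case_an")
    if ("ref_af" %in% names(variants)) {
      v <- ref_af[!is.na(ref_af)]
      if (any(v < 0 | v > 1)) stop("ref_af outside [0, 1]")
    }
  })
  variants
}

#' Write a variant table as TSV
#'
#' @param variants Variant data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Fraction of variants absent from the reference panel ("rare")
#'
#' A variant is rare iff its `ref_af` is missing -- it was never observed
#' in the reference population panel.
#'
#' @param variants Variant data.frame.
#' @param classFilter Consequence class to keep (default
#'   `"nonsynonymous"`); `NULL` keeps all.
#' @return List `n_rare`, `n_total`, `fraction`.
#' @export
rareFraction <- function(variants, classFilter = "nonsynonymous") {
  v <- variants
  if (!is.null(classFilter)) v <- v[v$consequence %in% classFilter, , drop = FALSE]
  if (nrow(v) == 0L) stop("no variant left after the consequence filter")
  rare <- if ("ref_af" %in% names(v)) is.na(v$ref_af) else rep(TRUE, nrow(v))
  list(n_rare = sum(rare), n_total = nrow(v), fraction = mean(rare))
}

#' Matched-gene permutation test of rare-variant enrichment in a module
#'
#' Observed statistic: the rare fraction among (class-filtered) variants
#' on the module's genes. Null: the same fraction on `|module|` genes drawn
#' from a covariate-matched background pool, `nPerm` times. Permutations
#' whose sampled genes carry no variants contribute a fraction of 0 (and
#' are counted in a message).
#'
#' @param moduleGenes Character vector of module genes.
#' @param variants Variant data.frame.
#' @param pool A [MatchedBackground] matched to the module genes.
#' @param nPerm Number of permutations.
#' @param seed Integer seed.
#' @param classFilter Consequence filter (default `"nonsynonymous"`).
#' @return List `observed`, `expected` (mean permuted fraction),
#'   `permuted`, `p`.
#' @export
rareEnrichmentPermutation <- function(moduleGenes, variants, pool, nPerm,
                                      seed, classFilter = "nonsynonymous") {
  nPerm <- .assertCount(nPerm, "nPerm")
  v <- variants
  if (!is.null(classFilter)) v <- v[v$consequence %in% classFilter, , drop = FALSE]
  rare <- is.na(v$ref_af)
  fracOn <- function(genes) {
    hit <- v$gene %in% genes
    if (!any(hit)) return(NA_real_)
    mean(rare[hit])
  }
  obs <- fracOn(moduleGenes)
  if (is.na(obs)) stop("no variant maps onto the module genes")
  genes <- poolGenes(pool)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(nPerm), function(i)
    fracOn(sample(genes, length(moduleGenes))), numeric(1))
  nEmpty <- sum(is.na(perm))
  if (nEmpty > 0L) {
    message(nEmpty, " permutation(s) sampled genes without variants; fraction set to 0")
    perm[is.na(perm)] <- 0
  }
  list(observed = obs, expected = mean(perm), permuted = perm,
       p = empiricalP(sum(perm >= obs), nPerm))
}

#' Per-variant case vs reference-population allele-frequency tests
#'
#' For each variant observed in the reference panel, reconstructs the
#' reference allele counts as `round(ref_af * ref_an)` out of `ref_an`
#' haplotypes, tests case counts against them with a two-sided Fisher's
#' exact test, applies BH across the variant family, and reports the genes
#' carrying at least one variant below `fdrTarget`. Variants missing
#' `ref_af` are excluded here (they are "rare" and handled by
#' [rareFraction()] / [rareEnrichmentPermutation()]).
#'
#' @param variants Variant data.frame.
#' @param fdrTarget Expected false-positive rate (default 0.1).
#' @param refAnDefault Reference haplotype count used when the table lacks
#'   a `ref_an` column (default 5008, a 1000-Genomes-scale panel).
#' @return List: `perVariant` (data.frame with `p`, `fdr`) and `genes`
#'   (data.frame `gene`, `n_variants`, `min_fdr`, `significant_variants`).
#' @export
afCaseVsReference <- function(variants, fdrTarget = 0.1,
                              refAnDefault = 5008L) {
  v <- variants[!is.na(variants$ref_af), , drop = FALSE]
  if (nrow(v) == 0L) stop("no variant with a reference allele frequency")
  refAn <- if ("ref_an" %in% names(v)) v$ref_an else rep(refAnDefault, nrow(v))
  if (any(is.na(refAn) | refAn <= 0)) stop("reference allele number must be positive")
  refAlt <- round(v$ref_af * refAn)
  p <- vapply(seq_len(nrow(v)), function(i)
    fisher2x2(matrix(c(v$case_alt[i], v$case_an[i] - v$case_alt[i],
                       refAlt[i], refAn[i] - refAlt[i]),
                     2L, 2L, byrow = TRUE)), numeric(1))
  v$p <- p
  v$fdr <- bhAdjust(p)
  sig <- v[v$fdr < fdrTarget, , drop = FALSE]
  genes <- if (nrow(sig) == 0L) {
    data.frame(gene = character(), n_variants = integer(),
               min_fdr = numeric(), significant_variants = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(split(sig, sig$gene), function(s)
      data.frame(gene = s$gene[1L], n_variants = nrow(s),
                 min_fdr = min(s$fdr),
                 significant_variants = paste(s$variant_id, collapse = ","),
                 stringsAsFactors = FALSE)))
  }
  rownames(genes) <- NULL
  list(perVariant = v, genes = genes[order(genes$min_fdr), , drop = FALSE])
}

# Location-scale t maximum-likelihood fit (location m, scale s, df nu),
# optimized over (m, log s, log nu) with Nelder-Mead from robust starts.
.fitT <- function(x) {
  negll <- function(par) {
    s <- exp(par[2L]); nu <- exp(par[3L])
    -sum(stats::dt((x - par[1L]) / s, df = nu, log = TRUE) - log(s))
  }
  start <- c(median(x), log(max(mad(x), 1e-8)), log(5))
  fit <- optim(start, negll, method = "Nelder-Mead",
               control = list(maxit = 2000L))
  list(m = fit$par[1L], s = exp(fit$par[2L]), df = exp(fit$par[3L]),
       convergence = fit$convergence)
}

#' Reciprocal-regression allele-frequency outliers
#'
#' Regresses case allele frequencies on control allele frequencies and
#' vice versa by ordinary least squares. In each direction the residuals
#' are modeled by a maximum-likelihood location-scale t-distribution, and
#' variants whose case-excess-oriented residual exceeds the fitted
#' `1 - tail` quantile are flagged; the reported outliers are the union
#' over both directions, with direction labels. (In the control-on-case
#' direction the residual is negated before flagging, so both directions
#' point at case excess -- variants with extreme allele-frequency imbalance
#' in the patient population.)
#'
#' @param variants Variant data.frame with `control_alt`, `control_an`.
#' @param tail Upper tail fraction (default 0.05).
#' @return data.frame per variant: `variant_id`, `gene`, `case_af`,
#'   `control_af`, `resid_case_on_control`, `resid_control_on_case`
#'   (case-excess-oriented), `outlier_case_on_control`,
#'   `outlier_control_on_case`, `outlier` (union). t-fit parameters are in
#'   `attr(, "fits")`.
#' @export
reciprocalRegressionOutliers <- function(variants, tail = 0.05) {
  need <- c("control_alt", "control_an")
  if (!all(need %in% names(variants)))
    stop("reciprocal regression needs control allele counts")
  v <- variants[!is.na(variants$control_alt) & !is.na(variants$control_an), ,
                drop = FALSE]
  if (nrow(v) < 20L) stop("need at least 20 variants with control counts")
  caseAF <- v$case_alt / v$case_an
  ctrlAF <- v$control_alt / v$control_an
  r1 <- residuals(lm(caseAF ~ ctrlAF))           # case excess = upper tail
  r2 <- -residuals(lm(ctrlAF ~ caseAF))          # oriented to case excess
  flag <- function(r) {
    if (sd(r) < 1e-12) {
      warning("zero residual variance: no outliers")
      return(list(flags = rep(FALSE, length(r)), fit = NULL))
    }
    fit <- .fitT(r)
    thr <- fit$m + fit$s * qt(1 - tail, df = fit$df)
    list(flags = r > thr, fit = fit)
  }
  f1 <- flag(r1)
  f2 <- flag(r2)
  out <- data.frame(variant_id = v$variant_id, gene = v$gene,
                    case_af = caseAF, control_af = ctrlAF,
                    resid_case_on_control = unname(r1),
                    resid_control_on_case = unname(r2),
                    outlier_case_on_control = f1$flags,
                    outlier_control_on_case = f2$flags,
                    outlier = f1$flags | f2$flags,
                    stringsAsFactors = FALSE)
  attr(out, "fits") <- list(case_on_control = f1$fit,
                            control_on_case = f2$fit, tail = tail)
  out
}

#' Candidate-gene concentration among top allele-frequency differences
#'
#' Sorts variants by decreasing |case AF - control AF| and computes, over a
#' grid of top-k cutoffs, the fraction of top-k variants whose gene belongs
#' to the candidate set. The statistic is the mean of that curve; its null
#' distribution resamples `|candidateGenes|` genes uniformly from the
#' module `nPerm` times.
#'
#' @param variants Variant data.frame with `control_alt`, `control_an`.
#' @param candidateGenes Candidate genes, a subset of `module`.
#' @param module Module gene set the candidates were found in.
#' @param kGrid Integer grid of top-k cutoffs; default 10 cuts spanning the
#'   top 2--20 percent of variants.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param level `"variant"` (default) scores each top variant;
#'   `"gene"` scores the distinct genes among the top variants.
#' @return List `curve` (data.frame `k`, `fraction`), `statistic`,
#'   `permuted`, `p`.
#' @export
afDifferenceRankCurve <- function(variants, candidateGenes, module,
                                  kGrid = NULL, nPerm = 1000L, seed = 1L,
                                  level = c("variant", "gene")) {
  level <- match.arg(level)
  if (!all(candidateGenes %in% module))
    stop("candidate genes must lie within the module")
  v <- variants[!is.na(variants$control_alt), , drop = FALSE]
  if (!all(c("control_alt", "control_an") %in% names(v)) || nrow(v) == 0L)
    stop("curve needs case and control allele counts")
  afDiff <- abs(v$case_alt / v$case_an - v$control_alt / v$control_an)
  ord <- order(-afDiff, v$variant_id)
  geneSorted <- v$gene[ord]
  if (is.null(kGrid))
    kGrid <- unique(pmax(1L, round(nrow(v) * seq(0.02, 0.20, length.out = 10L))))
  kGrid <- sort(unique(as.integer(kGrid)))
  if (min(kGrid) < 1L || max(kGrid) > nrow(v))
    stop("fewer variants than the largest k in the grid")
  curveStat <- function(cand) {
    fr <- vapply(kGrid, function(k) {
      top <- geneSorted[seq_len(k)]
      if (level == "gene") top <- unique(top)
      mean(top %in% cand)
    }, numeric(1))
    fr
  }
  obsCurve <- curveStat(candidateGenes)
  obs <- mean(obsCurve)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(nPerm), function(i)
    mean(curveStat(sample(module, length(candidateGenes)))), numeric(1))
  list(curve = data.frame(k = kGrid, fraction = obsCurve),
       statistic = obs, permuted = perm,
       p = empiricalP(sum(perm >= obs), nPerm))
}

#' Default coreness layer bins
#'
#' Periphery `{1}`, `{2}`, intermediate `{3-5}`, `{6-9}`, center `{>= 10}`.
#'
#' @return data.frame `lo`, `hi`, `label`.
#' @export
defaultCorenessBins <- function() {
  data.frame(lo = c(1L, 2L, 3L, 6L, 10L), hi = c(1, 2, 5, 9, Inf),
             label = c("K=1", "K=2", "3<=K<6", "6<=K<10", "K>=10"),
             stringsAsFactors = FALSE)
}

#' Data-driven coreness bins (periphery / intermediate / center)
#'
#' Splits observed coreness values at their tertiles into three layers.
#' Useful when a module's coreness range is too narrow for the fixed
#' [defaultCorenessBins()] to populate three layers.
#'
#' @param k Integer coreness values (e.g. of one module's genes).
#' @return data.frame `lo`, `hi`, `label` with three rows.
#' @export
corenessTertileBins <- function(k) {
  distinct <- sort(unique(k))
  if (length(distinct) < 3L) {
    warning("fewer than three distinct coreness values; layers degenerate")
    return(data.frame(lo = distinct, hi = c(distinct[-1L] - 1L, Inf),
                      label = paste0("K", distinct), stringsAsFactors = FALSE))
  }
  cf <- cumsum(table(k)) / length(k)
  b1 <- distinct[min(which(cf >= 1 / 3))]
  b2 <- distinct[min(which(cf >= 2 / 3))]
  # every layer must be populated: push cut points off the extremes
  if (b2 >= max(k)) b2 <- max(distinct[distinct < max(k)])
  if (b1 >= b2) b1 <- max(distinct[distinct < b2], min(k))
  if (b1 >= b2) { b1 <- distinct[1L]; b2 <- distinct[2L] }
  data.frame(lo = c(min(k), b1 + 1L, b2 + 1L), hi = c(b1, b2, Inf),
             label = c("periphery", "intermediate", "center"),
             stringsAsFactors = FALSE)
}

#' Mutated-gene fraction across coreness layers (U-shape burden test)
#'
#' Bins a module's genes by coreness, computes the fraction of mutated
#' genes per bin with hypergeometric enrichment and depletion p-values
#' (universe = module), and tests the U-shape contrast
#' `S = (f_top + f_bottom) - 2 * f_middle` -- mutated fractions in the
#' highest-K and lowest-K non-empty bins against the pooled middle bins --
#' by resampling `|mutatedGenes|` genes uniformly from the module.
#'
#' @param mutatedGenes Genes carrying significant variants (subset of
#'   `module`).
#' @param module Module gene set.
#' @param corenessMap A [CorenessMap] covering the module.
#' @param bins data.frame `lo`, `hi` (`label` optional); default
#'   [defaultCorenessBins()].
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List: `bins` (data.frame `label`, `lo`, `hi`, `n_genes`,
#'   `n_mutated`, `fraction`, `p_enrich`, `p_deplete`), `S`, `permuted`,
#'   `p`. Empty bins carry `NA` fractions and are excluded from `S`.
#' @export
corenessBurdenProfile <- function(mutatedGenes, module, corenessMap,
                                  bins = defaultCorenessBins(),
                                  nPerm = 1000L, seed = 1L) {
  if (!all(mutatedGenes %in% module))
    stop("mutated genes must lie within the module")
  k <- geneCoreness(corenessMap)
  miss <- setdiff(module, names(k))
  if (length(miss) > 0L)
    stop("module gene(s) without coreness, e.g. ", miss[1L])
  k <- k[module]
  if (!"label" %in% names(bins))
    bins$label <- sprintf("[%g,%g]", bins$lo, bins$hi)
  binOf <- function(kv) {
    idx <- vapply(kv, function(one)
      which(one >= bins$lo & one <= bins$hi)[1L], integer(1))
    if (anyNA(idx)) stop("coreness value outside every bin")
    idx
  }
  gBin <- binOf(k)
  mut <- module %in% mutatedGenes
  nMut <- sum(mut)
  tab <- do.call(rbind, lapply(seq_len(nrow(bins)), function(b) {
    inB <- gBin == b
    n <- sum(inB)
    km <- sum(mut[inB])
    data.frame(label = bins$label[b], lo = bins$lo[b], hi = bins$hi[b],
               n_genes = n, n_mutated = km,
               fraction = if (n > 0L) km / n else NA_real_,
               p_enrich = if (n > 0L)
                 hypergeomUpperTail(km, n, nMut, length(module)) else NA_real_,
               p_deplete = if (n > 0L)
                 hypergeomLowerTail(km, n, nMut, length(module)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  nonEmpty <- which(tab$n_genes > 0L)
  uShape <- function(mutFlag) {
    fr <- vapply(nonEmpty, function(b)
      mean(mutFlag[gBin == b]), numeric(1))
    if (length(nonEmpty) < 3L) return(0)
    top <- fr[length(fr)]
    bottom <- fr[1L]
    mid <- nonEmpty[-c(1L, length(nonEmpty))]
    fMid <- mean(mutFlag[gBin %in% mid])
    (top + bottom) - 2 * fMid
  }
  S <- uShape(mut)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(nPerm), function(i) {
    pm <- logical(length(module))
    pm[sample.int(length(module), nMut)] <- TRUE
    uShape(pm)
  }, numeric(1))
  list(bins = tab, S = S, permuted = perm,
       p = empiricalP(sum(perm >= S), nPerm))
}

#' Bias of a core gene set toward one expression group within a module
#'
#' Hypergeometric upper-tail test with the module as universe, the
#' expression group as marked genes, and the core set as the draw.
#'
#' @param coreGenes High-coreness genes (subset of `module`).
#' @param group1 Expression-group genes (subset of `module`).
#' @param module Module gene set.
#' @return One-row data.frame `k`, `n`, `K_set`, `N_u`, `p`.
#' @export
coreGroupBias <- function(coreGenes, group1, module) {
  if (!all(coreGenes %in% module) || !all(group1 %in% module))
    stop("core genes and group must lie within the module")
  k <- length(intersect(coreGenes, group1))
  data.frame(k = k, n = length(coreGenes), K_set = length(group1),
             N_u = length(module),
             p = hypergeomUpperTail(k, length(coreGenes), length(group1),
                                    length(module)))
}

#' Spearman correlation between coreness and expression
#'
#' Rank correlation (average ranks for ties, two-sided asymptotic p)
#' between genes' coreness and their expression in one tissue.
#'
#' @param corenessMap A [CorenessMap].
#' @param expression Named numeric vector of per-gene expression values.
#' @return List `rho`, `p`, `n`.
#' @export
corenessExpressionCorrelation <- function(corenessMap, expression) {
  k <- geneCoreness(corenessMap)
  common <- intersect(names(k), names(expression))
  if (length(common) < 10L)
    stop("need at least 10 genes with both coreness and expression")
  kv <- as.numeric(k[common])
  ev <- as.numeric(expression[common])
  if (sd(kv) == 0 || sd(ev) == 0) stop("constant vector: correlation undefined")
  ct <- suppressWarnings(cor.test(kv, ev, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(common))
}
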