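# Seeded generators for every input shape the pipeline consumes, each with
# planted ground truth. Defaults are desk-scale study conditions: a modular
# network of 10 blocks of 30 genes, covariate-confounded disease lists,
# two-group tissue expression, and case/control variant tables with planted
# allele-frequency shifts.

#' Planted-partition random interaction network
#'
#' Stochastic block model: within-block edges with probability `pIn`,
#' between-block edges with probability `pOut`. Isolated nodes are removed
#' (and recorded), matching the interactome loading contract.
#'
#' @param nBlocks Number of planted modules (default 10).
#' @param blockSizes Single size or vector per block (default 30).
#' @param pIn,pOut Edge probabilities (need `0 <= pOut < pIn <= 1`).
#' @param seed Integer seed.
#' @return List `graph` (igraph, vertices `G0001`...), `truth` (list with
#'   `block` named assignment, parameters, `removed_isolated`).
#' @export
genModularNetwork <- function(nBlocks = 10L, blockSizes = 30L,
                              pIn = 0.3, pOut = 0.005, seed = 1L) {
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1))
    stop("need 0 <= pOut < pIn <= 1")
  sizes <- if (length(blockSizes) == 1L) rep(blockSizes, nBlocks) else blockSizes
  if (length(sizes) != nBlocks) stop("blockSizes must have length 1 or nBlocks")
  n <- sum(sizes)
  if (n < 2L) stop("parameters imply an (almost) empty graph")
  set.seed(as.integer(seed))
  pm <- matrix(pOut, nBlocks, nBlocks)
  diag(pm) <- pIn
  g <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
  genes <- sprintf("G%04d", seq_len(n))
  igraph::V(g)$name <- genes
  block <- setNames(rep(seq_len(nBlocks), sizes), genes)
  iso <- genes[igraph::degree(g) == 0L]
  if (length(iso) > 0L) g <- igraph::delete_vertices(g, iso)
  if (igraph::vcount(g) == 0L) stop("parameters imply an empty graph")
  list(graph = g,
       truth = list(kind = "modular_network",
                    block = as.list(block[igraph::V(g)$name]),
                    removed_isolated = iso,
                    params = list(nBlocks = nBlocks, blockSizes = sizes,
                                  pIn = pIn, pOut = pOut, seed = seed)))
}

#' Gene annotation table with an optional covariate-confounded disease set
#'
#' CDS lengths are log-normal, GC contents beta-distributed. Disease genes
#' are sampled with probability proportional to
#' `cds_length ^ log2(confoundFactor)`: at `confoundFactor = 1` the set is
#' unbiased, at larger values it carries the longer-CDS bias that a matched
#' background must neutralize.
#'
#' @param genes Character vector of gene symbols.
#' @param diseaseSetSize Number of disease genes to plant.
#' @param confoundFactor >= 1; strength of the CDS-length bias (default 1).
#' @param cdsMeanlog,cdsSdlog Log-normal CDS-length parameters (defaults
#'   log(1500) and 0.7, a human-CDS-like spread).
#' @param gcShape1,gcShape2 Beta parameters for GC content (defaults 26 and
#'   24, centered near 0.52).
#' @param seed Integer seed.
#' @return List `annotation` (data.frame `gene`, `cds_length`,
#'   `gc_content`, `is_disease`), `truth`.
#' @export
genGeneAnnotation <- function(genes, diseaseSetSize, confoundFactor = 1,
                              cdsMeanlog = log(1500), cdsSdlog = 0.7,
                              gcShape1 = 26, gcShape2 = 24, seed = 1L) {
  if (confoundFactor < 1) stop("confoundFactor must be >= 1")
  if (diseaseSetSize > length(genes))
    stop("diseaseSetSize exceeds the number of genes")
  set.seed(as.integer(seed))
  cds <- pmax(90L, round(rlnorm(length(genes), cdsMeanlog, cdsSdlog)))
  gc <- rbeta(length(genes), gcShape1, gcShape2)
  w <- cds ^ log2(confoundFactor)
  disease <- sample(genes, diseaseSetSize, prob = w / sum(w))
  ann <- data.frame(gene = genes, cds_length = cds, gc_content = gc,
                    is_disease = genes %in% disease,
                    stringsAsFactors = FALSE)
  list(annotation = ann,
       truth = list(kind = "gene_annotation", disease_genes = sort(disease),
                    params = list(diseaseSetSize = diseaseSetSize,
                                  confoundFactor = confoundFactor,
                                  cdsMeanlog = cdsMeanlog, cdsSdlog = cdsSdlog,
                                  gcShape1 = gcShape1, gcShape2 = gcShape2,
                                  seed = seed)))
}

#' Expression matrix with a planted tissue-specific gene group
#'
#' Log-normal noise around a common baseline; `group1Genes` gain
#' `effectSize` (log scale) in `t1Samples` only, `baselineHighGenes` are
#' elevated everywhere (the ubiquitous group). All values are positive.
#'
#' @param genes,samples Row / column names.
#' @param group1Genes Genes forming the tissue-specific group.
#' @param t1Samples Samples (tissue sections) where group 1 is elevated.
#' @param effectSize Log-scale elevation of group 1 in T1 (default 2).
#' @param noiseSd Log-scale noise sd (default 0.4).
#' @param group2Genes The ubiquitous counterpart group: elevated by
#'   `highLog` in every sample but dipping by `effectSize / 2` in
#'   `t1Samples` (default none).
#' @param baselineHighGenes Genes elevated in every sample (default none);
#'   must not overlap `group1Genes`.
#' @param baselineLog Log baseline expression (default `log(5)`).
#' @param highLog Log elevation of `baselineHighGenes` (default 1.5).
#' @param seed Integer seed.
#' @return List `matrix` (genes x samples), `truth`.
#' @export
genExpressionMatrix <- function(genes, samples, group1Genes, t1Samples,
                                effectSize = 2, noiseSd = 0.4,
                                group2Genes = character(),
                                baselineHighGenes = character(),
                                baselineLog = log(5), highLog = 1.5,
                                seed = 1L) {
  if (!all(group1Genes %in% genes) || !all(t1Samples %in% samples))
    stop("group1Genes / t1Samples must be subsets of genes / samples")
  if (!all(group2Genes %in% genes)) stop("group2Genes must be among genes")
  if (length(intersect(group1Genes, c(group2Genes, baselineHighGenes))) > 0L ||
      length(intersect(group2Genes, baselineHighGenes)) > 0L)
    stop("group 1, group 2 and baseline-high roles must not overlap")
  set.seed(as.integer(seed))
  mu <- matrix(baselineLog, length(genes), length(samples),
               dimnames = list(genes, samples))
  mu[group1Genes, t1Samples] <- mu[group1Genes, t1Samples] + effectSize
  if (length(group2Genes) > 0L) {
    mu[group2Genes, ] <- mu[group2Genes, ] + highLog
    mu[group2Genes, t1Samples] <- mu[group2Genes, t1Samples] - effectSize / 2
  }
  mu[baselineHighGenes, ] <- mu[baselineHighGenes, ] + highLog
  m <- exp(mu + matrix(rnorm(length(mu), 0, noiseSd), nrow(mu)))
  list(matrix = m,
       truth = list(kind = "expression_matrix",
                    group1_genes = sort(group1Genes),
                    group2_genes = sort(group2Genes),
                    t1_samples = sort(t1Samples),
                    baseline_high_genes = sort(baselineHighGenes),
                    params = list(effectSize = effectSize, noiseSd = noiseSd,
                                  baselineLog = baselineLog, highLog = highLog,
                                  seed = seed)))
}

#' Case/control variant table with planted allele-frequency shifts
#'
#' Per gene a Poisson number of variants. Each variant's reference allele
#' frequency is drawn from a site-frequency-spectrum-like skewed Beta
#' (truncated to [0.001, 0.5]) or is missing ("rare", absent from the
#' panel) with probability `rareRate` (`plantedRareRate` on planted genes).
#' Case and control alt counts are binomial at the variant's underlying
#' frequency, except that planted genes' nonsynonymous case counts use
#' `min(1, af + afShift)`. Rare variants segregate at a low latent
#' frequency (`latentRareAf`) that the reference panel missed.
#'
#' @param genes Gene symbols.
#' @param plantedGenes Genes receiving the case AF shift (default none).
#' @param afShift Case allele-frequency excess on planted genes (default
#'   0.1).
#' @param variantsPerGeneMean Poisson mean variant count per gene (default 3).
#' @param rareRate Probability a variant is absent from the reference panel
#'   (default 0.1).
#' @param plantedRareRate Rare rate on planted genes (default `rareRate`).
#' @param caseAn,controlAn Case / control allele numbers (defaults 1010 and
#'   982: a 505/491-subject cohort).
#' @param refAn Reference panel haplotypes (default 5008).
#' @param latentRareAf Latent frequency of panel-absent variants (default
#'   0.002).
#' @param refAfDist Function(n) drawing n reference AFs; default truncated
#'   Beta(0.2, 2).
#' @param consequenceProbs Probabilities for nonsynonymous / silent / other
#'   (default 0.6 / 0.3 / 0.1).
#' @param seed Integer seed.
#' @return List `variants` (data.frame in [readVariantTable()] layout),
#'   `truth`.
#' @export
genVariantTable <- function(genes, plantedGenes = character(), afShift = 0.1,
                            variantsPerGeneMean = 3, rareRate = 0.1,
                            plantedRareRate = rareRate,
                            caseAn = 1010L, controlAn = 982L, refAn = 5008L,
                            latentRareAf = 0.002,
                            refAfDist = NULL,
                            consequenceProbs = c(0.6, 0.3, 0.1),
                            seed = 1L) {
  if (afShift < 0) stop("afShift must be >= 0")
  .assertProb(c(rareRate, plantedRareRate), "rareRate")
  if (caseAn <= 0) stop("caseAn must be positive")
  if (!all(plantedGenes %in% genes)) stop("planted genes must be among genes")
  set.seed(as.integer(seed))
  if (is.null(refAfDist))
    refAfDist <- function(n) pmin(pmax(rbeta(n, 0.2, 2), 0.001), 0.5)
  nv <- rpois(length(genes), variantsPerGeneMean)
  # a planted frequency-shifted gene must be observable: guarantee it at
  # least one variant, and below, at least one nonsynonymous one
  nv[genes %in% plantedGenes] <- pmax(1L, nv[genes %in% plantedGenes])
  gene <- rep(genes, nv)
  n <- length(gene)
  if (n == 0L) stop("no variants generated; increase variantsPerGeneMean")
  planted <- gene %in% plantedGenes
  cons <- sample(c("nonsynonymous", "silent", "other"), n, replace = TRUE,
                 prob = consequenceProbs)
  firstOfPlanted <- !duplicated(gene) & planted
  cons[firstOfPlanted] <- "nonsynonymous"
  rareP <- ifelse(planted, plantedRareRate, rareRate)
  isRare <- runif(n) < rareP
  # a requested frequency shift must be observable against the reference
  # panel: the guaranteed nonsynonymous variant of each planted gene stays
  # panel-present when a shift is planted
  if (afShift > 0) isRare[firstOfPlanted] <- FALSE
  af <- refAfDist(n)
  af[isRare] <- latentRareAf
  shifted <- planted & cons == "nonsynonymous"
  caseAf <- ifelse(shifted, pmin(1, af + afShift), af)
  v <- data.frame(
    variant_id = sprintf("v%05d", seq_len(n)),
    gene = gene,
    consequence = cons,
    case_alt = rbinom(n, caseAn, caseAf),
    case_an = caseAn,
    control_alt = rbinom(n, controlAn, af),
    control_an = controlAn,
    ref_af = ifelse(isRare, NA_real_, af),
    ref_an = refAn,
    stringsAsFactors = FALSE)
  list(variants = validateVariantTable(v),
       truth = list(kind = "variant_table",
                    planted_genes = sort(plantedGenes),
                    rare_variants = v$variant_id[isRare],
                    shifted_variants = v$variant_id[shifted],
                    params = list(afShift = afShift,
                                  variantsPerGeneMean = variantsPerGeneMean,
                                  rareRate = rareRate,
                                  plantedRareRate = plantedRareRate,
                                  caseAn = caseAn, controlAn = controlAn,
                                  refAn = refAn, latentRareAf = latentRareAf,
                                  seed = seed)))
}

#' Matched case-control expression pairs with planted extreme DE genes
#'
#' Per pair, the control column is log-normal around a per-gene baseline;
#' the case column shares the baseline but multiplies planted genes by
#' `foldChange` (up) or its inverse (down).
#'
#' @param genes Gene symbols.
#' @param nPairs Number of matched pairs (default 6).
#' @param plantedUp,plantedDown Genes planted up- / down-regulated.
#' @param foldChange Planted fold change (> 1; default 3).
#' @param noiseSd Log-scale noise sd (default 0.2).
#' @param baselineLog Log-scale baseline mean (default `log(10)`).
#' @param seed Integer seed.
#' @return List `case`, `control` (genes x pairs matrices), `truth`.
#' @export
genPairedCaseControlExpression <- function(genes, nPairs = 6L,
                                           plantedUp = character(),
                                           plantedDown = character(),
                                           foldChange = 3, noiseSd = 0.2,
                                           baselineLog = log(10), seed = 1L) {
  if (foldChange <= 1) stop("foldChange must exceed 1")
  bad <- setdiff(c(plantedUp, plantedDown), genes)
  if (length(bad) > 0L) stop("planted gene(s) not in genes, e.g. ", bad[1L])
  set.seed(as.integer(seed))
  base <- rnorm(length(genes), baselineLog, 0.5)
  pairIds <- sprintf("pair%02d", seq_len(nPairs))
  noise <- function() matrix(rnorm(length(genes) * nPairs, 0, noiseSd),
                             length(genes))
  control <- exp(base + noise())
  shift <- numeric(length(genes))
  shift[genes %in% plantedUp] <- log(foldChange)
  shift[genes %in% plantedDown] <- -log(foldChange)
  case <- exp(base + shift + noise())
  dimnames(control) <- dimnames(case) <- list(genes, pairIds)
  list(case = case, control = control,
       truth = list(kind = "paired_expression",
                    planted_up = sort(plantedUp),
                    planted_down = sort(plantedDown),
                    params = list(nPairs = nPairs, foldChange = foldChange,
                                  noiseSd = noiseSd, baselineLog = baselineLog,
                                  seed = seed)))
}

#' Composite synthetic scene with planted truth in every layer
#'
#' One coherent data set exercising the whole pipeline: a planted-partition
#' network; a disease gene set concentrated in one planted module and
#' confounded by CDS length; an expression matrix giving half of that
#' module a tissue-specific profile; a variant table with AF-shifted genes
#' inside the module; and matched case-control expression pairs with
#' planted extreme-DE genes in the module.
#'
#' @param seed Integer seed; every layer derives its own seed from it.
#' @param nBlocks,blockSizes,pIn,pOut Network parameters (defaults 10
#'   blocks of 30, 0.3 / 0.005).
#' @param diseaseInModule Disease genes planted inside module block 1
#'   (default 20).
#' @param diseaseOutside Disease genes sampled outside it (default 20).
#' @param confoundFactor CDS-length confounding of the disease set
#'   (default 2).
#' @param nSamples Expression samples, split into two tissue groups
#'   (default 60).
#' @param nBurdenGenes AF-shifted genes planted in the module (default 10).
#' @param afShift Case AF excess (default 0.1).
#' @param nDePairs Matched expression pairs (default 6).
#' @param nDeGenes Planted extreme-DE genes in the module (default 10).
#' @return List `graph`, `annotation`, `diseaseGenes`, `expression`,
#'   `variants`, `casePairs`, `controlPairs`, `truth`.
#' @export
genSyntheticScene <- function(seed = 1L, nBlocks = 10L, blockSizes = 30L,
                              pIn = 0.3, pOut = 0.005,
                              diseaseInModule = 20L, diseaseOutside = 20L,
                              confoundFactor = 2, nSamples = 60L,
                              nBurdenGenes = 10L, afShift = 0.1,
                              nDePairs = 6L, nDeGenes = 10L) {
  seed <- as.integer(seed)
  net <- genModularNetwork(nBlocks, blockSizes, pIn, pOut,
                           seed = deriveSeed(seed, 1L))
  genes <- igraph::V(net$graph)$name
  block <- unlist(net$truth$block)
  moduleGenes <- names(block)[block == 1L]

  # disease set: planted module enrichment plus scattered background genes
  set.seed(deriveSeed(seed, 2L))
  diseaseGenes <- c(sample(moduleGenes, min(diseaseInModule, length(moduleGenes))),
                    sample(setdiff(genes, moduleGenes), diseaseOutside))

  # annotation over the network genes; CDS confounding applies to the
  # disease set independently of where it sits on the network
  annGen <- genGeneAnnotation(genes, diseaseSetSize = length(diseaseGenes),
                              confoundFactor = confoundFactor,
                              seed = deriveSeed(seed, 3L))
  ann <- annGen$annotation
  # overwrite the generator's covariate-biased choice with the planted,
  # module-concentrated set, keeping its covariate bias by construction:
  # planted disease genes inherit elevated CDS lengths
  ann$is_disease <- ann$gene %in% diseaseGenes
  if (confoundFactor > 1) {
    idx <- ann$is_disease
    ann$cds_length[idx] <- round(ann$cds_length[idx] * confoundFactor^0.5)
  }

  samples <- sprintf("S%03d", seq_len(nSamples))
  t1 <- samples[seq_len(nSamples %/% 2L)]
  group1 <- moduleGenes[seq_len(length(moduleGenes) %/% 2L)]
  group2 <- setdiff(moduleGenes, group1)
  expr <- genExpressionMatrix(genes, samples, group1Genes = group1,
                              t1Samples = t1, group2Genes = group2,
                              seed = deriveSeed(seed, 4L))

  set.seed(deriveSeed(seed, 5L))
  burden <- sample(moduleGenes, nBurdenGenes)
  vt <- genVariantTable(genes, plantedGenes = burden, afShift = afShift,
                        rareRate = 0.10, plantedRareRate = 0.30,
                        seed = deriveSeed(seed, 6L))

  set.seed(deriveSeed(seed, 7L))
  deUp <- sample(setdiff(moduleGenes, character(0)), nDeGenes)
  pairs <- genPairedCaseControlExpression(genes, nPairs = nDePairs,
                                          plantedUp = deUp,
                                          seed = deriveSeed(seed, 8L))

  list(graph = net$graph, annotation = ann, diseaseGenes = diseaseGenes,
       expression = expr$matrix, variants = vt$variants,
       casePairs = pairs$case, controlPairs = pairs$control,
       truth = list(kind = "scene", seed = seed,
                    block = net$truth$block,
                    module_genes = moduleGenes,
                    disease_genes = sort(diseaseGenes),
                    group1_genes = sort(group1),
                    t1_samples = sort(t1),
                    burden_genes = sort(burden),
                    de_genes = sort(deUp),
                    params = list(nBlocks = nBlocks, blockSizes = blockSizes,
                                  pIn = pIn, pOut = pOut,
                                  diseaseInModule = diseaseInModule,
                                  diseaseOutside = diseaseOutside,
                                  confoundFactor = confoundFactor,
                                  nSamples = nSamples,
                                  nBurdenGenes = nBurdenGenes,
                                  afShift = afShift, nDePairs = nDePairs,
                                  nDeGenes = nDeGenes)))
}

#' Serialize / restore planted ground truth
#'
#' Ground truth lists are written as JSON so a generated scene can be
#' regenerated and checked byte-for-byte.
#'
#' @param truth Ground-truth list from a generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @return For `readGroundTruth`, the restored list.
#' @export
readGroundTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
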