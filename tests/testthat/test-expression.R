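test_that("per-gene z-scoring is exact, invertible, and drops constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), d = c(2, 8, 4))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(normalizePerGene(m), "constant")
  se <- suppressWarnings(normalizePerGene(m))
  z <- SummarizedExperiment::assay(se, 1)
  expect_equal(rownames(z), c("a", "d"))
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 1, sd)), c(1, 1))
  rd <- SummarizedExperiment::rowData(se)
  back <- z * rd$gene_sd + rd$gene_mean
  expect_equal(unname(back), unname(m[c("a", "d"), ]), tolerance = 1e-9)
  expect_error(
    normalizePerGene(matrix(1, 1, 3, dimnames = list("x", paste0("s", 1:3)))),
    "constant")
})

test_that("expression reader averages multi-probe rows and attaches annotations", {
  tf <- withr::local_tempfile()
  writeLines(c("gene\ts1\ts2", "A\t1\t2", "A\t3\t4", "B\t5\t6"), tf)
  se <- readExpressionMatrix(tf)
  m <- SummarizedExperiment::assay(se, 1)
  expect_equal(unname(m["A", ]), c(2, 3))
  expect_equal(unname(m["B", ]), c(5, 6))
  tfa <- withr::local_tempfile()
  writeLines(c("sample\ttissue_label", "s1\tcortex", "s2\tcallosum"), tfa)
  se2 <- readExpressionMatrix(tf, tfa)
  expect_equal(SummarizedExperiment::colData(se2)$tissue_label,
               c("cortex", "callosum"))
  # round trip through the writer
  tf2 <- withr::local_tempfile()
  writeExpressionMatrix(m, tf2)
  m2 <- SummarizedExperiment::assay(readExpressionMatrix(tf2), 1)
  expect_equal(m2, m)
})

test_that("dichotomization recovers planted two-block structure with stable labels", {
  genes <- sprintf("g%02d", 1:30)
  samples <- sprintf("s%02d", 1:24)
  ge <- genExpressionMatrix(genes, samples, group1Genes = genes[1:14],
                           t1Samples = samples[1:12],
                           group2Genes = genes[15:30],
                           effectSize = 0.5, noiseSd = 0.1, seed = 5)
  d <- dichotomize(ge$matrix)
  gg <- geneGroups(d)
  sc <- sampleClusters(d)
  expect_equal(ari(gg, ifelse(names(gg) %in% ge$truth$group1_genes, 1, 2)), 1)
  expect_equal(ari(as.integer(factor(sc)),
                   ifelse(names(sc) %in% ge$truth$t1_samples, 1, 2)), 1)
  # orientation: group 1 is the T1-elevated group
  expect_true(all(gg[ge$truth$group1_genes] == 1L))
  expect_true(all(sc[ge$truth$t1_samples] == "T1"))

  # duplicated genes receive identical labels
  m <- ge$matrix
  m2 <- rbind(m, dupA = m["g01", ], dupB = m["g15", ])
  d2 <- dichotomize(m2)
  expect_equal(geneGroups(d2)[["dupA"]], geneGroups(d2)[["g01"]])
  expect_equal(geneGroups(d2)[["dupB"]], geneGroups(d2)[["g15"]])

  # sample order must not change the gene grouping
  d3 <- dichotomize(m[, rev(samples)])
  expect_equal(ari(geneGroups(d3)[names(gg)], gg), 1)

  expect_error(dichotomize(m[1:3, ]), "at least 4")
  expect_error(dichotomize(matrix(1, 5, 5,
                                  dimnames = list(paste0("g", 1:5),
                                                  paste0("s", 1:5)))))
})

test_that("tau follows its closed form, bounds, and scale invariance", {
  expect_equal(tauIndex(c(5, 5, 5, 5)), 0)
  expect_equal(tauIndex(c(7, 0, 0)), 1)
  expect_equal(tauIndex(c(1, 0.5, 0)), 0.75)
  expect_warning(tauIndex(c(0, 0, 0)), "all-zero")
  expect_true(is.na(suppressWarnings(tauIndex(c(0, 0, 0)))))
  expect_error(tauIndex(c(-1, 2)), "non-negative")
  set.seed(3)
  for (i in 1:20) {
    x <- rexp(10)
    expect_equal(tauIndex(x), tauIndex(x * runif(1, 0.1, 50)))
    expect_gte(tauIndex(x), 0)
    expect_lte(tauIndex(x), 1)
  }
  # matrix dispatch
  m <- rbind(u = c(5, 5, 5, 5), h = c(7, 0, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  expect_equal(unname(tauIndex(m)), c(0, 1))
})

test_that("expression breadth counts active samples at pooled quantile cutoffs", {
  m <- matrix(1:100, nrow = 10, byrow = TRUE,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:10)))
  b <- expressionBreadth(m, 0.5)
  # pooled median of 1..100 is 50.5: genes 1-5 entirely below, 6-10 above
  expect_equal(unname(b[, 1]), c(0L, 0L, 0L, 0L, 0L, 10L, 10L, 10L, 10L, 10L))
  bAll <- expressionBreadth(m)
  expect_true(all(bAll[, "q0.50"] <= bAll[, "q0.25"]))
  expect_true(all(bAll[, "q0.25"] <= bAll[, "q0.15"]))
  # a uniformly high gene is active everywhere
  m2 <- rbind(m, hi = rep(1000, 10))
  expect_equal(unname(expressionBreadth(m2, 0.5)["hi", 1]), 10L)
})

test_that("group-vs-background comparisons are calibrated and powered", {
  genes <- sprintf("g%03d", 1:400)
  samples <- sprintf("s%02d", 1:6)
  # null: group drawn from the same distribution as the background
  pNull <- unlist(lapply(1:20, function(s) {
    ge <- genExpressionMatrix(genes, samples, group1Genes = character(0),
                              t1Samples = character(0), noiseSd = 0.3,
                              seed = 900 + s)
    set.seed(s)
    grp <- sample(genes, 40)
    groupVsBackground(ge$matrix, grp, backgroundSize = 200, seed = s)$p
  }))
  expect_gte(mean(pNull > 0.05), 0.9)

  # one strongly shifted sample is detected there
  ge <- genExpressionMatrix(genes, samples, group1Genes = genes[1:40],
                            t1Samples = samples[1], effectSize = 0.9,
                            noiseSd = 0.3, seed = 1)
  res <- groupVsBackground(ge$matrix, genes[1:40], backgroundSize = 200,
                           seed = 2)
  expect_lt(res$p[res$sample == samples[1]], 1e-4)
  expect_equal(res$direction[res$sample == samples[1]], 1L)
  expect_error(groupVsBackground(ge$matrix, genes), "background")
})

test_that("co-expression QC separates latent-factor networks from noise", {
  net <- genModularNetwork(nBlocks = 4, blockSizes = 25, pIn = 0.3,
                           pOut = 0.01, seed = 3)
  genes <- igraph::V(net$graph)$name
  block <- unlist(net$truth$block)[genes]
  # adjacent genes mostly share a block; give each block a latent factor
  set.seed(4)
  samples <- 30
  latent <- matrix(rnorm(4 * samples), 4)
  m <- 5 + 0.9 * latent[block, ] + matrix(rnorm(length(genes) * samples, 0, 0.5),
                                          length(genes))
  dimnames(m) <- list(genes, paste0("s", 1:samples))
  qc <- coexpressionQC(net$graph, m, nRandomPairs = 500, seed = 5)
  expect_lt(qc$p, 0.01)
  expect_gt(qc$median_interacting, qc$median_random)

  # independent noise: calibrated
  pNull <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    mN <- matrix(rexp(length(genes) * 20), length(genes),
                 dimnames = list(genes, paste0("s", 1:20)))
    coexpressionQC(net$graph, mN, nRandomPairs = 300, seed = 2000 + s)$p
  }, numeric(1))
  expect_gte(mean(pNull > 0.05), 0.9)

  # constant gene excluded
  mC <- m
  mC[1, ] <- 3
  expect_message(coexpressionQC(net$graph, mC, nRandomPairs = 100, seed = 1),
                 "constant")
})

test_that("extreme DE calling flags planted genes and respects its filters", {
  # toy pair: 10 genes, one at fold change 3, rest near 1
  ca <- matrix(c(30, rep(10, 9)), ncol = 1,
               dimnames = list(paste0("g", 1:10), "p1"))
  co <- matrix(rep(10, 10), ncol = 1, dimnames = dimnames(ca))
  de <- extremeDECall(ca, co)
  expect_equal(anyExtremeGenes(de), "g1")

  # identical matrices: nothing flagged
  de0 <- extremeDECall(co, co)
  expect_length(anyExtremeGenes(de0), 0)

  # low-expression genes are absent from their pair
  ca2 <- ca; co2 <- co
  ca2["g2", 1] <- 0.1; co2["g2", 1] <- 0.2
  de2 <- extremeDECall(ca2, co2)
  expect_false("g2" %in% de2$gene)

  coWide <- cbind(p1 = co[, 1], p2 = co[, 1])
  rownames(coWide) <- rownames(co)
  expect_error(extremeDECall(ca, coWide), "paired")
  expect_error(extremeDECall(ca, co, fcMin = 0.9), "fcMin")

  # planted recovery across pairs; flags invariant to gene order
  genes <- sprintf("g%03d", 1:300)
  set.seed(9)
  planted <- sample(genes, 6)
  pe <- genPairedCaseControlExpression(genes, nPairs = 6,
                                       plantedUp = planted[1:4],
                                       plantedDown = planted[5:6],
                                       foldChange = 3, noiseSd = 0.15,
                                       seed = 10)
  de3 <- extremeDECall(pe$case, pe$control)
  expect_true(all(planted %in% anyExtremeGenes(de3)))
  shuffle <- sample(nrow(pe$case))
  de4 <- extremeDECall(pe$case[shuffle, ], pe$control[shuffle, ])
  expect_setequal(anyExtremeGenes(de4), anyExtremeGenes(de3))

  # null pairs: flagged fraction stays near the quantile budget
  pe0 <- genPairedCaseControlExpression(genes, nPairs = 2, foldChange = 3,
                                        noiseSd = 0.15, seed = 11)
  de5 <- extremeDECall(pe0$case, pe0$control)
  expect_lte(length(anyExtremeGenes(de5)) / length(genes), 0.05 * 2 + 0.02)
})

test_that("DE module enrichment reduces to the hypergeometric tail", {
  uni <- sprintf("u%03d", 1:200)
  mod <- uni[1:30]
  # DE set equals the module: minimal p for the sizes
  res <- deModuleEnrichment(mod, mod, uni)
  expect_equal(res$p, hypergeomUpperTail(30, 30, 30, 200))
  # disjoint: p = 1
  expect_equal(deModuleEnrichment(uni[31:60], mod, uni)$p, 1)
  expect_error(deModuleEnrichment(mod, c(mod, "zz"), uni), "universe")
  # planted power: 20% DE inside a 100-gene module vs 5% outside (N = 5000)
  bigUni <- sprintf("b%04d", 1:5000)
  bigMod <- bigUni[1:100]
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    deg <- c(sample(bigMod, 20), sample(bigUni[-(1:100)], 245))
    deModuleEnrichment(deg, bigMod, bigUni)$p < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
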