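mkVariants <- function(n, gene = sprintf("g%03d", seq_len(n)),
                       caseAlt = 1L, caseAn = 1000L,
                       ctrlAlt = NULL, ctrlAn = 1000L,
                       refAf = rep(0.01, n), cons = "nonsynonymous") {
  df <- data.frame(variant_id = sprintf("v%04d", seq_len(n)), gene = gene,
                   consequence = cons, case_alt = caseAlt, case_an = caseAn,
                   ref_af = refAf, ref_an = 5008L, stringsAsFactors = FALSE)
  if (!is.null(ctrlAlt)) {
    df$control_alt <- ctrlAlt
    df$control_an <- ctrlAn
  }
  df
}

test_that("variant table IO validates invariants and preserves passthrough columns", {
  v <- mkVariants(5)
  v$gerp <- runif(5)
  v$ref_af[2] <- NA
  tf <- withr::local_tempfile()
  writeVariantTable(v, tf)
  back <- readVariantTable(tf)
  expect_equal(back$gerp, v$gerp)
  expect_true(is.na(back$ref_af[2]))
  bad <- v
  bad$case_alt[1] <- 2000L
  expect_error(validateVariantTable(bad), "case_alt")
  bad2 <- v
  bad2$variant_id[2] <- bad2$variant_id[1]
  expect_error(validateVariantTable(bad2), "duplicated")
})

test_that("rare fraction counts panel-absent variants within a consequence class", {
  v <- mkVariants(20)
  v$ref_af[1:7] <- NA
  rf <- rareFraction(v)
  expect_equal(rf$fraction, 0.35)
  expect_equal(rf$n_rare, 7)
  # the printed cohort arithmetic: 30 rare of 153 nonsynonymous
  v2 <- mkVariants(153)
  v2$ref_af[1:30] <- NA
  expect_equal(round(rareFraction(v2)$fraction * 100, 1), 19.6)
  # all observed in the panel
  expect_equal(rareFraction(mkVariants(10))$fraction, 0)
  # silent variants are a separate family
  v3 <- rbind(mkVariants(10), mkVariants(5, cons = "silent"))
  v3$variant_id <- sprintf("w%04d", 1:15)
  expect_equal(rareFraction(v3, "silent")$n_total, 5)
  expect_error(rareFraction(v3, "missense"), "no variant")
})

test_that("rare-variant enrichment permutation is powered and calibrated", {
  genes <- sprintf("G%04d", 1:1000)
  # planted: module gene variants 20% rare vs 10% elsewhere
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    module <- sample(genes, 50)
    vt <- genVariantTable(genes, plantedGenes = module, afShift = 0,
                          variantsPerGeneMean = 4, rareRate = 0.10,
                          plantedRareRate = 0.20, seed = 100 + s)$variants
    res <- suppressMessages(rareEnrichmentPermutation(
      module, vt, trivialPool(genes, module), nPerm = 999, seed = 200 + s))
    res$p <= 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # null: uniform p (KS), observed below all permutations gives p = 1
  vt0 <- genVariantTable(genes, variantsPerGeneMean = 4, rareRate = 0.15,
                         seed = 5)$variants
  ps <- vapply(1:200, function(i) {
    set.seed(4000 + i)
    module <- sample(genes, 60)
    suppressMessages(rareEnrichmentPermutation(
      module, vt0, trivialPool(genes, module), nPerm = 199,
      seed = 8000 + i)$p)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_true(all(ps > 0))
})

test_that("case-vs-reference AF tests recover planted shifts at FDR 0.1", {
  # a strong single variant among 100 nulls survives BH
  v <- mkVariants(101)
  v$case_alt <- rbinom(101, 50, 0.01)
  v$case_an <- 50L
  v$case_alt[1] <- 10L
  v$case_an[1] <- 50L
  res <- afCaseVsReference(v, fdrTarget = 0.1)
  expect_lt(res$perVariant$p[1], 1e-6)
  expect_true(v$gene[1] %in% res$genes$gene)

  # matched depth, matched frequency: nothing reported
  v2 <- mkVariants(50, caseAlt = 10L, caseAn = 1000L, refAf = 0.01)
  res2 <- afCaseVsReference(v2)
  expect_equal(nrow(res2$genes), 0)

  # missing ref_af is excluded (routed to the rare-variant analyses)
  v3 <- mkVariants(30)
  v3$ref_af[1:10] <- NA
  expect_equal(nrow(afCaseVsReference(v3)$perVariant), 20)

  # planted-generator recovery: >= 8/10 genes across 20 seeds
  genes <- sprintf("G%04d", 1:300)
  rec <- vapply(1:20, function(s) {
    set.seed(s)
    planted <- sample(genes, 10)
    vt <- genVariantTable(genes, plantedGenes = planted, afShift = 0.1,
                          seed = 1000 + s)$variants
    length(intersect(afCaseVsReference(vt, 0.1)$genes$gene, planted))
  }, numeric(1))
  expect_true(all(rec >= 8))

  # no planted shift: false-positive genes stay at or below the FDR budget
  fp <- vapply(1:10, function(s) {
    vt <- genVariantTable(genes, afShift = 0, seed = 2000 + s)$variants
    nrow(afCaseVsReference(vt, 0.1)$genes)
  }, numeric(1))
  expect_lte(mean(fp) / length(genes), 0.1)

  # symmetry: swapping case and reconstructed reference roles keeps p
  vS <- mkVariants(1, caseAlt = 7L, caseAn = 100L, refAf = 0.02)
  pA <- afCaseVsReference(vS)$perVariant$p
  refAlt <- round(0.02 * 5008)
  vSw <- data.frame(variant_id = "x", gene = "g", consequence = "nonsynonymous",
                    case_alt = refAlt, case_an = 5008L,
                    ref_af = 7 / 100, ref_an = 100L)
  pB <- afCaseVsReference(vSw)$perVariant$p
  expect_equal(pA, pB, tolerance = 1e-9)
})

test_that("reciprocal regression flags planted case-excess variants, not nulls", {
  mkAf <- function(n, shiftIdx = integer(0), shift = 0.1, seed = 1) {
    set.seed(seed)
    af <- pmin(pmax(rbeta(n, 0.2, 2), 0.001), 0.5)
    caseAf <- af
    caseAf[shiftIdx] <- pmin(1, af[shiftIdx] + shift)
    v <- mkVariants(n, caseAlt = rbinom(n, 1010, caseAf), caseAn = 1010L,
                    ctrlAlt = rbinom(n, 982, af), ctrlAn = 982L, refAf = af)
    v
  }
  res <- t(vapply(1:20, function(s) {
    v <- mkAf(510, shiftIdx = 1:10, seed = s)
    out <- reciprocalRegressionOutliers(v, tail = 0.05)
    c(sum(out$outlier[1:10]), mean(out$outlier[-(1:10)]))
  }, numeric(2)))
  expect_true(all(res[, 1] >= 8))
  expect_lte(mean(res[, 2]), 0.05)
  # type-I rate within [tail/2, 2 tail] on pure null
  expect_gte(mean(res[, 2]), 0.025)

  # calibration on exact t-distributed residuals at n = 2000
  set.seed(42)
  n <- 2000
  x <- runif(n, 0, 0.5)
  y <- x + 0.02 * rt(n, df = 6)
  v <- mkVariants(n, caseAlt = pmax(0L, round(y * 1e6)), caseAn = 1000000L,
                  ctrlAlt = round(x * 1e6), ctrlAn = 1000000L, refAf = x)
  fr <- mean(reciprocalRegressionOutliers(v, tail = 0.05)$outlier)
  expect_gte(fr, 0.03)
  expect_lte(fr, 0.07)

  # perfectly collinear frequencies: degenerate, no outliers
  vC <- mkVariants(30, caseAlt = (1:30) * 10L, caseAn = 1000L,
                   ctrlAlt = (1:30) * 10L, ctrlAn = 1000L)
  w <- capture_warnings(outC <- reciprocalRegressionOutliers(vC))
  expect_match(w, "zero residual", all = FALSE)
  expect_false(any(outC$outlier))
  expect_error(reciprocalRegressionOutliers(mkVariants(5, ctrlAlt = 1L)),
               "at least 20")
})

test_that("AF-difference rank curve concentrates planted candidates at the top", {
  genes <- sprintf("G%04d", 1:500)
  # candidate set = module: curve is identically 1 and p = 1
  vt <- genVariantTable(genes, variantsPerGeneMean = 4, seed = 6)$variants
  resAll <- afDifferenceRankCurve(vt, genes, genes, nPerm = 99, seed = 1)
  expect_true(all(resAll$curve$fraction == 1))
  expect_equal(resAll$p, 1)

  # planted: candidates carry the largest AF shifts
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    cand <- sample(genes, 38)
    vtp <- genVariantTable(genes, plantedGenes = cand, afShift = 0.15,
                           variantsPerGeneMean = 4, seed = 100 + s)$variants
    afDifferenceRankCurve(vtp, cand, genes, nPerm = 999,
                          seed = 200 + s)$p <= 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # null calibration: random candidate sets give uniform p
  ps <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    cand <- sample(genes, 38)
    afDifferenceRankCurve(vt, cand, genes, nPerm = 199, seed = 9000 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  expect_error(afDifferenceRankCurve(vt, "nope", genes), "within the module")
  expect_error(afDifferenceRankCurve(vt, genes[1], genes,
                                     kGrid = c(2, nrow(vt) + 1)),
               "fewer variants")
})

test_that("coreness burden profile detects layer bias and conserves fractions", {
  set.seed(7)
  g <- igraph::sample_fitness_pl(400, 3000, exponent.out = 2.3)
  igraph::V(g)$name <- sprintf("G%04d", 1:400)
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  km <- kcoreDecompose(g)
  module <- igraph::V(g)$name
  kv <- geneCoreness(km)[module]
  bins <- corenessTertileBins(kv)
  expect_equal(nrow(bins), 3)

  # concentration in the extreme layers: U-shape detected
  top <- names(kv)[kv >= bins$lo[3]]
  bottom <- names(kv)[kv <= bins$hi[1]]
  hits <- vapply(1:20, function(s) {
    set.seed(300 + s)
    mut <- unique(c(sample(top, 40), sample(bottom, 30), sample(module, 10)))
    res <- corenessBurdenProfile(mut, module, km, bins = bins, nPerm = 199,
                                 seed = 400 + s)
    (res$p < 0.05) && (res$bins$p_enrich[3] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # conservation: size-weighted bin fractions equal the overall rate
  set.seed(1)
  mut <- sample(module, 60)
  res <- corenessBurdenProfile(mut, module, km, bins = bins, nPerm = 99,
                               seed = 2)
  expect_equal(sum(res$bins$fraction * res$bins$n_genes) / length(module),
               length(mut) / length(module))

  # degenerate: everything mutated
  resAll <- corenessBurdenProfile(module, module, km, bins = bins,
                                  nPerm = 49, seed = 3)
  expect_true(all(resAll$bins$fraction == 1))
  expect_equal(resAll$S, 0)

  # null calibration
  ps <- vapply(1:200, function(i) {
    set.seed(6000 + i)
    corenessBurdenProfile(sample(module, 80), module, km, bins = bins,
                          nPerm = 199, seed = 10000 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("core-group bias matches enumeration on a small module", {
  module <- paste0("m", 1:20)
  group1 <- module[1:10]
  core <- module[1:5]
  res <- coreGroupBias(core, group1, module)
  expect_equal(res$p, oracleHyperUpper(5, 5, 10, 20), tolerance = 1e-12)
  expect_equal(coreGroupBias(core, module, module)$p, 1)
  expect_gt(coreGroupBias(module[11:14], group1, module)$p, 0.9)
  expect_error(coreGroupBias(c(core, "zz"), group1, module), "within")
})

test_that("coreness-expression correlation handles monotone and null profiles", {
  k <- new("CorenessMap",
           coreness = setNames(rep(1:10, each = 3), sprintf("g%02d", 1:30)))
  exprUp <- setNames(as.numeric(1:30), sprintf("g%02d", 1:30))
  up <- corenessExpressionCorrelation(k, exprUp)
  expect_gt(up$rho, 0.9)
  down <- corenessExpressionCorrelation(k, rev(unname(exprUp)) |>
                                          setNames(names(exprUp)))
  expect_lt(down$rho, -0.9)
  # perfectly monotone in K (ties only within equal-K groups)
  exprK <- setNames(as.numeric(rep(1:10, each = 3)), names(geneCoreness(k)))
  expect_equal(corenessExpressionCorrelation(k, exprK)$rho, 1)
  # independent expression: small |rho|
  rhos <- vapply(1:20, function(s) {
    set.seed(s)
    kk <- new("CorenessMap",
              coreness = setNames(sample(1:12, 300, TRUE),
                                  sprintf("h%03d", 1:300)))
    ee <- setNames(rexp(300), sprintf("h%03d", 1:300))
    abs(corenessExpressionCorrelation(kk, ee)$rho)
  }, numeric(1))
  expect_gte(mean(rhos < 0.15), 0.9)
  expect_error(corenessExpressionCorrelation(k, exprUp[1:5]), "at least 10")
  expect_error(corenessExpressionCorrelation(k, setNames(rep(1, 30),
                                                         names(exprUp))),
               "constant")
})
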