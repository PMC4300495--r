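# Pipeline orchestration: flat key = value config with [sections], stage
# toggles, deterministic per-stage seeding, TSV + JSON report bundle.

.configRegistry <- list(
  global = c("seed", "out_dir"),
  inputs = c("edge_list", "annotation", "disease_genes", "expression",
             "variants", "case_pairs", "control_pairs"),
  stages = c("simulate", "modularize", "null_test", "enrich", "match",
             "dichotomize", "specificity", "de_call", "burden", "outliers"),
  params = c("min_module_size", "fdr_cut", "n_perm", "n_random",
             "balance_threshold", "fc_min", "upper_q", "lower_q", "min_expr",
             "tail", "n_restarts", "swap_multiplier", "background_size"),
  simulate = c("n_blocks", "block_sizes", "p_in", "p_out",
               "disease_in_module", "disease_outside", "confound_factor",
               "n_samples", "n_burden_genes", "af_shift", "n_de_pairs",
               "n_de_genes")
)

.defaultConfig <- function() {
  list(
    global = list(seed = 1L, out_dir = "netmodule_run"),
    inputs = list(),
    stages = list(simulate = FALSE, modularize = TRUE, null_test = FALSE,
                  enrich = TRUE, match = TRUE, dichotomize = TRUE,
                  specificity = TRUE, de_call = TRUE, burden = TRUE,
                  outliers = TRUE),
    params = list(min_module_size = 6L, fdr_cut = 0.1, n_perm = 1000L,
                  n_random = 20L, balance_threshold = 0.05, fc_min = 2,
                  upper_q = 0.975, lower_q = 0.025, min_expr = 1,
                  tail = 0.05, n_restarts = 10L, swap_multiplier = 10,
                  background_size = 1000L),
    simulate = list(n_blocks = 10L, block_sizes = 30L, p_in = 0.3,
                    p_out = 0.005, disease_in_module = 20L,
                    disease_outside = 20L, confound_factor = 2,
                    n_samples = 60L, n_burden_genes = 10L, af_shift = 0.1,
                    n_de_pairs = 6L, n_de_genes = 10L)
  )
}

.coerceConfigValue <- function(raw) {
  low <- tolower(raw)
  if (low %in% c("true", "false")) return(low == "true")
  num <- suppressWarnings(as.numeric(raw))
  if (!is.na(num)) {
    if (num == round(num) && abs(num) < .Machine$integer.max)
      return(as.integer(num))
    return(num)
  }
  raw
}

#' Read a pipeline configuration file
#'
#' Flat `key = value` lines under `[section]` headers; `#` starts a
#' comment. Unknown sections or keys are rejected; unset keys fall back to
#' package defaults.
#'
#' @param path Config file path.
#' @return Nested list (sections of key/value pairs) with defaults filled
#'   in.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- .defaultConfig()
  section <- NULL
  for (i in seq_along(lines <- readLines(path, warn = FALSE))) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.+\\]$", line)) {
      section <- sub("^\\[(.+)\\]$", "\\1", line)
      if (!section %in% names(.configRegistry))
        stop("unknown config section [", section, "] at line ", i)
      next
    }
    if (is.null(section)) stop("key outside any [section] at line ", i)
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line ", i, ": ", line)
    key <- trimws(kv[1L])
    if (!key %in% .configRegistry[[section]])
      stop("unknown key '", key, "' in section [", section, "] at line ", i)
    cfg[[section]][[key]] <- .coerceConfigValue(trimws(paste(kv[-1L],
                                                             collapse = "=")))
  }
  cfg
}

#' Write a pipeline configuration file
#'
#' @param config Nested config list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  out <- character(0)
  for (sec in names(config)) {
    if (length(config[[sec]]) == 0L) next
    out <- c(out, sprintf("[%s]", sec))
    for (key in names(config[[sec]])) {
      v <- config[[sec]][[key]]
      out <- c(out, sprintf("%s = %s",
                            key, if (is.logical(v)) tolower(as.character(v))
                            else .fmtNum(v)))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

# Canonical single-string form of a config, for hashing and echoing.
.configString <- function(cfg) {
  parts <- unlist(lapply(names(cfg), function(sec)
    vapply(names(cfg[[sec]]), function(k)
      sprintf("%s.%s=%s", sec, k,
              paste(as.character(cfg[[sec]][[k]]), collapse = ",")), "")))
  paste(sort(parts), collapse = ";")
}

# Stage seeds fan out from the global seed by a fixed derivation:
# stage i (in the canonical stage order) gets deriveSeed(seed, 100 + i).
.stageOrder <- c("simulate", "modularize", "null_test", "enrich", "match",
                 "dichotomize", "specificity", "de_call", "burden",
                 "outliers")

stageSeed <- function(seed, stage) {
  idx <- match(stage, .stageOrder)
  if (is.na(idx)) stop("unknown stage: ", stage)
  deriveSeed(seed, 100L + idx)
}

.writeSceneInputs <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    edge_list = file.path(dir, "network.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    disease_genes = file.path(dir, "disease_genes.txt"),
    expression = file.path(dir, "expression.tsv"),
    variants = file.path(dir, "variants.tsv"),
    case_pairs = file.path(dir, "case_pairs.tsv"),
    control_pairs = file.path(dir, "control_pairs.tsv")
  )
  writeEdgeList(scene$graph, paths$edge_list)
  write.table(scene$annotation, paths$annotation, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(sort(scene$diseaseGenes), paths$disease_genes)
  writeExpressionMatrix(scene$expression, paths$expression)
  writeVariantTable(scene$variants, paths$variants)
  writeExpressionMatrix(scene$casePairs, paths$case_pairs)
  writeExpressionMatrix(scene$controlPairs, paths$control_pairs)
  writeGroundTruth(scene$truth, file.path(dir, "truth.json"))
  paths
}

.stageFail <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the integrative module-localization pipeline
#'
#' Executes the configured stages in dependency order: (optionally)
#' simulate a synthetic scene, decompose the network into first-level
#' modules plus coreness layers, test modularity against rewiring nulls,
#' scan modules for disease-set enrichment, confirm the top module with a
#' covariate-matched permutation test, dichotomize its expression and
#' score tissue specificity, call extreme differential expression in
#' matched pairs, and compute variant-burden statistics (rare fractions,
#' per-variant AF tests, coreness burden profile, reciprocal-regression
#' outliers). Each stage writes its tables before the next starts; a
#' failure aborts with a stage-labeled error.
#'
#' @param config Config list ([readPipelineConfig()]) or a path to a
#'   config file.
#' @param outDir Output directory (overrides `global.out_dir`).
#' @return A run-report list (stage results, provenance); also written by
#'   [makeReport()] as a TSV bundle plus `summary.json` under `outDir`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- config
  if (is.null(outDir)) outDir <- cfg$global$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$global$seed)
  st <- cfg$stages
  pr <- cfg$params
  results <- list()
  warningsLog <- character(0)

  inputs <- cfg$inputs
  if (isTRUE(st$simulate)) {
    sim <- cfg$simulate
    scene <- tryCatch(
      genSyntheticScene(seed = stageSeed(seed, "simulate"),
                        nBlocks = sim$n_blocks, blockSizes = sim$block_sizes,
                        pIn = sim$p_in, pOut = sim$p_out,
                        diseaseInModule = sim$disease_in_module,
                        diseaseOutside = sim$disease_outside,
                        confoundFactor = sim$confound_factor,
                        nSamples = sim$n_samples,
                        nBurdenGenes = sim$n_burden_genes,
                        afShift = sim$af_shift, nDePairs = sim$n_de_pairs,
                        nDeGenes = sim$n_de_genes),
      error = function(e) .stageFail("simulate", e))
    inputs <- .writeSceneInputs(scene, file.path(outDir, "inputs"))
    results$simulate <- list(
      inputs = lapply(inputs, function(p) file.path("inputs", basename(p))))
  }

  needInput <- function(key, stage) {
    p <- inputs[[key]]
    if (is.null(p) || !file.exists(p))
      stop(sprintf("pipeline stage '%s' failed: missing input '%s'%s",
                   stage, key,
                   if (is.null(p)) "" else paste0(" (", p, ")")),
           call. = FALSE)
    p
  }

  graph <- partition <- corenessMap <- topModuleGenes <- NULL
  topModuleId <- NA_integer_

  if (isTRUE(st$modularize)) {
    graph <- tryCatch(
      suppressMessages(readEdgeList(needInput("edge_list", "modularize"))),
      error = function(e) .stageFail("modularize", e))
    partition <- tryCatch(
      louvainPartition(graph, seed = stageSeed(seed, "modularize"),
                       nRestarts = pr$n_restarts),
      error = function(e) .stageFail("modularize", e))
    corenessMap <- kcoreDecompose(graph)
    writePartition(partition, file.path(outDir, "partition.tsv"), graph)
    writeCoreness(corenessMap, file.path(outDir, "coreness.tsv"))
    results$modularize <- list(
      n_nodes = igraph::vcount(graph), n_edges = igraph::ecount(graph),
      n_modules = max(moduleAssignment(partition)) + 1L,
      q = modularityQ(partition))
  }

  if (isTRUE(st$null_test)) {
    if (is.null(graph)) stop("pipeline stage 'null_test' failed: needs modularize")
    nt <- tryCatch(
      modularityNullTest(graph, nRandom = pr$n_random,
                         seed = stageSeed(seed, "null_test"),
                         nSwapMultiplier = pr$swap_multiplier,
                         nRestarts = pr$n_restarts),
      error = function(e) .stageFail("null_test", e))
    results$null_test <- list(q_observed = observedModularity(nt),
                              q_null_max = max(nullModularities(nt)),
                              n_random = nt@nRandom,
                              p_empirical = pEmpirical(nt))
  }

  diseaseGenes <- NULL
  if (isTRUE(st$enrich)) {
    if (is.null(partition)) stop("pipeline stage 'enrich' failed: needs modularize")
    diseaseGenes <- readGeneList(needInput("disease_genes", "enrich"))
    scan <- tryCatch(
      moduleSetScan(partition, sets = list(disease = diseaseGenes),
                    minModuleSize = pr$min_module_size),
      error = function(e) .stageFail("enrich", e))
    write.table(scan, file.path(outDir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    topModuleId <- scan$module_id[1L]
    topModuleGenes <- moduleGenes(partition, topModuleId)
    results$enrich <- list(top_module_id = topModuleId,
                           top_module_size = length(topModuleGenes),
                           top_fdr = scan$fdr[1L], top_p = scan$p[1L],
                           n_tested_modules = length(unique(scan$module_id)))
  }

  if (isTRUE(st$match)) {
    if (is.null(topModuleGenes)) stop("pipeline stage 'match' failed: needs enrich")
    ann <- tryCatch(readGeneAnnotation(needInput("annotation", "match")),
                    error = function(e) .stageFail("match", e))
    res <- tryCatch({
      pool <- buildMatchedBackground(diseaseGenes, ann,
                                     balanceThreshold = pr$balance_threshold,
                                     seed = stageSeed(seed, "match"))
      mt <- matchedPermutationTest(topModuleGenes, diseaseGenes, pool,
                                   nPerm = pr$n_perm,
                                   seed = stageSeed(seed, "match"))
      list(pool_size = length(poolGenes(pool)),
           balance = as.list(balancePValues(pool)),
           observed_overlap = mt$observed,
           expected_overlap = mean(mt$permuted), p_matched = mt$p)
    }, error = function(e) .stageFail("match", e))
    results$match <- res
  }

  dichotomy <- NULL
  exprMat <- NULL
  if (isTRUE(st$dichotomize) || isTRUE(st$specificity)) {
    se <- tryCatch(
      readExpressionMatrix(needInput("expression", "dichotomize")),
      error = function(e) .stageFail("dichotomize", e))
    exprMat <- .exprMatrix(se)
  }
  if (isTRUE(st$dichotomize)) {
    if (is.null(topModuleGenes))
      stop("pipeline stage 'dichotomize' failed: needs enrich")
    common <- intersect(topModuleGenes, rownames(exprMat))
    dichotomy <- tryCatch(
      dichotomize(exprMat[common, , drop = FALSE]),
      error = function(e) .stageFail("dichotomize", e))
    gg <- geneGroups(dichotomy)
    write.table(data.frame(gene = names(gg), group = unname(gg)),
                file.path(outDir, "dichotomy_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sc <- sampleClusters(dichotomy)
    write.table(data.frame(sample = names(sc), cluster = unname(sc)),
                file.path(outDir, "dichotomy_samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$dichotomize <- list(n_group1 = sum(gg == 1L),
                                n_group2 = sum(gg == 2L),
                                n_t1 = sum(sc == "T1"), n_t2 = sum(sc == "T2"))
  }

  if (isTRUE(st$specificity)) {
    res <- tryCatch({
      tau <- tauIndex(exprMat)
      breadth <- expressionBreadth(exprMat)
      out <- data.frame(gene = rownames(exprMat), tau = unname(tau),
                        breadth, check.names = FALSE)
      write.table(out, file.path(outDir, "specificity.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      r <- list(median_tau = median(tau, na.rm = TRUE))
      if (!is.null(dichotomy)) {
        gg <- geneGroups(dichotomy)
        t1 <- tau[names(gg)[gg == 1L]]
        t2 <- tau[names(gg)[gg == 2L]]
        wt <- suppressWarnings(wilcox.test(t1, t2))
        r$tau_group1_median <- median(t1, na.rm = TRUE)
        r$tau_group2_median <- median(t2, na.rm = TRUE)
        r$tau_wilcox_p <- wt$p.value
      }
      r
    }, error = function(e) .stageFail("specificity", e))
    results$specificity <- res
  }

  deGenes <- NULL
  if (isTRUE(st$de_call)) {
    res <- tryCatch({
      ca <- .exprMatrix(readExpressionMatrix(needInput("case_pairs", "de_call")))
      co <- .exprMatrix(readExpressionMatrix(needInput("control_pairs", "de_call")))
      de <- extremeDECall(ca, co, fcMin = pr$fc_min, upperQ = pr$upper_q,
                          lowerQ = pr$lower_q, minExpr = pr$min_expr)
      write.table(de, file.path(outDir, "de_calls.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      deGenes <- anyExtremeGenes(de)
      r <- list(n_de_genes = length(deGenes))
      if (!is.null(topModuleGenes) && !is.null(graph)) {
        enr <- deModuleEnrichment(deGenes, topModuleGenes,
                                  igraph::V(graph)$name)
        r$module_de_overlap <- enr$k
        r$module_de_p <- enr$p
      }
      r
    }, error = function(e) .stageFail("de_call", e))
    results$de_call <- res
  }

  variants <- NULL
  if (isTRUE(st$burden) || isTRUE(st$outliers)) {
    variants <- tryCatch(
      readVariantTable(needInput("variants", "burden")),
      error = function(e) .stageFail("burden", e))
  }
  if (isTRUE(st$burden)) {
    res <- tryCatch({
      moduleVars <- variants[variants$gene %in% topModuleGenes, , drop = FALSE]
      rf <- rareFraction(moduleVars)
      af <- afCaseVsReference(variants, fdrTarget = pr$fdr_cut)
      write.table(af$perVariant, file.path(outDir, "af_tests.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(af$genes, file.path(outDir, "burden_genes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      mutated <- intersect(af$genes$gene, topModuleGenes)
      r <- list(rare_fraction = rf$fraction, n_rare = rf$n_rare,
                n_nonsyn = rf$n_total,
                n_burden_genes = nrow(af$genes),
                n_burden_in_module = length(mutated))
      if (!is.null(inputs$annotation) && file.exists(inputs$annotation)) {
        ann <- readGeneAnnotation(inputs$annotation)
        modPool <- buildMatchedBackground(
          intersect(topModuleGenes, ann$gene), ann,
          balanceThreshold = pr$balance_threshold,
          seed = stageSeed(seed, "burden"))
        re <- rareEnrichmentPermutation(topModuleGenes, variants, modPool,
                                        nPerm = pr$n_perm,
                                        seed = stageSeed(seed, "burden"))
        r$rare_expected <- re$expected
        r$rare_enrichment_p <- re$p
      }
      if (length(mutated) > 0L && !is.null(corenessMap)) {
        kMod <- geneCoreness(corenessMap)[topModuleGenes]
        bins <- defaultCorenessBins()
        nOcc <- vapply(seq_len(nrow(bins)), function(b)
          sum(kMod >= bins$lo[b] & kMod <= bins$hi[b]) > 0L, logical(1))
        if (sum(nOcc) < 3L)
          bins <- suppressWarnings(corenessTertileBins(kMod))
        prof <- corenessBurdenProfile(mutated, topModuleGenes, corenessMap,
                                      bins = bins, nPerm = pr$n_perm,
                                      seed = stageSeed(seed, "burden"))
        write.table(prof$bins, file.path(outDir, "coreness_burden.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        r$ushape_S <- prof$S
        r$ushape_p <- prof$p
      }
      r
    }, error = function(e) .stageFail("burden", e))
    results$burden <- res
  }

  if (isTRUE(st$outliers)) {
    res <- tryCatch({
      out <- reciprocalRegressionOutliers(variants, tail = pr$tail)
      write.table(out, file.path(outDir, "af_outliers.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      r <- list(n_outlier_variants = sum(out$outlier),
                n_outlier_genes = length(unique(out$gene[out$outlier])))
      if (!is.null(topModuleGenes)) {
        og <- unique(out$gene[out$outlier])
        r$n_outlier_in_module <- length(intersect(og, topModuleGenes))
      }
      r
    }, error = function(e) .stageFail("outliers", e))
    results$outliers <- res
  }

  report <- list(
    results = results,
    provenance = list(
      package_version = as.character(packageVersion("NetModule")),
      seed = seed,
      config = cfg,
      config_hash = .hashString(.configString(cfg)),
      stage_seeds = setNames(
        lapply(.stageOrder, function(s) stageSeed(seed, s)), .stageOrder)
    ),
    warnings = warningsLog
  )
  makeReport(report, outDir)
  report
}

#' Serialize a run report (JSON summary)
#'
#' Writes `summary.json` with stable key order and fixed-precision
#' numbers, so identical configurations yield byte-identical summaries.
#' Stage tables are written as TSV by the stages themselves.
#'
#' @param report Run-report list from [runPipeline()].
#' @param outDir Output directory.
#' @return Path of the JSON summary, invisibly.
#' @export
makeReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) {
    if (is.list(x)) return(lapply(x, fmt))
    if (is.double(x) && length(x) == 1L && !is.na(x))
      return(as.numeric(.fmtNum(x)))
    x
  }
  path <- file.path(outDir, "summary.json")
  json <- jsonlite::toJSON(fmt(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}
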