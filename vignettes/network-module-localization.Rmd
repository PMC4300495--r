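---
title: "Methods: localizing disease genes on interaction-network modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localizing disease genes on interaction-network modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, the tunable parameters, the
synthetic-data generators, and the numerical and design choices behind
`NetModule`. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## 1. Network decomposition

**Model.** The interactome is an undirected simple graph over gene symbols.
Loading (`readEdgeList`) drops self-interactions, collapses duplicate and
reversed-duplicate records, and removes nodes left without edges; curation
direction is ignored because physical interaction is symmetric. Partition
quality is Newman–Girvan modularity

$$Q = \sum_c \left[\frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2\right],$$

with $m$ the edge count, $e_c$ the intra-module edges and $d_c$ the degree
sum of module $c$.

**First-level partitioning.** `louvainPartition` runs the multilevel greedy
heuristic and keeps the partition after the *first* complete
local-move-plus-aggregation level, i.e. the finest modular scale, rather
than the fully coarsened final level. The finest scale is the appropriate
operating point when downstream analyses interrogate individual mid-sized
modules: further aggregation merges small modules into large ones whose
gene-set enrichments are diluted. Greedy local moves depend on the node
order, so the heuristic is restarted (default `nRestarts = 10`) under
seeded random orders and the first-level partition with the highest $Q$ is
kept. Restarting is the standard remedy for order dependence in greedy
community detection; it leaves the "first level" semantics untouched
because each restart is itself a complete first level. With a fixed seed
the result is fully deterministic, and module ids are canonicalized to
contiguous integers from 0.

No resolution parameter is exposed: the first-level convention already
fixes the scale, and adding a resolution knob would make partitions
incomparable across runs.

**Null model.** `modularityNullTest` compares the observed $Q$ against
degree-preserving rewired copies (double-edge swaps, default
`nSwapMultiplier = 10` attempted swaps per edge, swaps creating self-loops
or duplicate edges rejected). Degree preservation is essential: modularity
correlates with degree heterogeneity, so an Erdős–Rényi null would
overstate significance. The empirical p-value is
$(1 + \#\{Q_\text{null} \ge Q_\text{obs}\})/(1 + n_\text{random})$
throughout the package — the add-one convention never reports 0, so a
claim like "p < 1/n from n permutations with zero exceedances" is
deliberately not reproducible here; the full null vector is returned so
any alternative reading can be checked.

**Coreness.** `kcoreDecompose` assigns each gene the largest $k$ such that
it survives iterative deletion of all nodes of degree < $k$. $K = 1$ is
the periphery; high $K$ is the network center. `subclusterModule` re-runs
first-level partitioning on one module's induced subgraph to expose
sub-complexes; genes in edge-less induced subgraphs become singleton
sub-clusters with an `NA` modularity (modularity is undefined at $m = 0$).

## 2. Enrichment with covariate-matched backgrounds

Hypergeometric upper-tail tests (`hypergeomUpperTail`, exact distribution
function, stable in log space) quantify module–gene-set overlap; the
universe defaults to the network's node set and is configurable to a
genome-wide list, because both conventions are legitimate and give
different baselines. Fisher's exact test (`fisher2x2`) is used two-sided
for ratio comparisons between two gene groups; enrichment scans are
one-sided because "enrichment" is a directional hypothesis.
Benjamini–Hochberg correction is applied within each scan invocation —
one analysis, one family — not globally across analyses.

**Matched backgrounds.** Disease gene lists are biased toward long, well
studied genes, and long genes also accumulate more variants; enrichment
against an unmatched background would partly measure that bias.
`buildMatchedBackground` builds, per covariate (CDS length in base pairs,
GC content as a fraction), a candidate pool of non-target genes inside the
target's [2.5, 97.5] percentile range, then trims the extreme decile on
the imbalanced side until a Wilcoxon rank-sum test against the target
exceeds `balanceThreshold` (default 0.05); the final pool is the
intersection across covariates, re-trimmed if intersecting broke balance.
Matching is pool-level (distributional balance), not per-gene caliper
pairing: the downstream consumer is a sampling distribution, which only
needs the pool's covariate law to match the target's. If the pool shrinks
below the target size the function stops and advises relaxing the
threshold rather than silently returning an unbalanced pool.

`matchedPermutationTest` then draws pseudo-target sets of the target's
size from the pool and compares module overlaps; `sizeThresholdScan`
counts enriched modules across minimum-size thresholds using a single BH
family fixed at the smallest threshold, which both keeps counts comparable
across thresholds and makes them provably monotone.

## 3. Expression analysis

**Normalization.** "Relative abundance across sections" is implemented as
per-gene z-scoring (mean 0, sd 1 across samples); the per-gene centers and
scales are retained so the transform is invertible. Constant genes carry
no relative signal and are dropped with a warning. Multiple probes mapped
to one gene are averaged at read time.

**Dichotomization.** `dichotomize` clusters z-scored genes with distance
1 − Pearson correlation and samples with Euclidean distance, average
linkage for both — the field's default choices for expression heatmaps
(correlation captures profile shape for genes; Euclidean captures overall
level for samples). Both trees are cut at exactly two clusters because the
biological question is a two-group contrast (tissue-specific vs
ubiquitous); a height-based cut could return one or many clusters and
break the contract. Labels are fixed by a deterministic convention: the
(gene group, sample cluster) cell with the highest mean z-score defines
(group 1, T1), so group 1 is always "the genes elevated in T1".

**Specificity.** The tissue-specificity index
$\tau = \sum_i (1 - x_i/\max_j x_j)/(N-1)$ is 0 for uniform profiles, 1
for one-tissue expression, scale-invariant, and undefined (returned `NA`
with a warning) for all-zero profiles. Expression breadth counts samples
at or above pooled-distribution quantile cutoffs (defaults 15%, 25%, 50%
of all values across genes and samples); quantiles use R's default linear
interpolation, fixed here for reproducibility.

**Extreme differential expression.** `extremeDECall` works per matched
case–control pair: genes below `minExpr` (default 1, FPKM-like units) in
both members of a pair are unquantifiable and excluded for that pair; fold
changes are $(case + \varepsilon)/(control + \varepsilon)$ with
$\varepsilon = 0.01$ to stabilize ratios when one member is near zero. A
gene is up-extreme in a pair iff its fold change exceeds both the absolute
floor `fcMin` (default 2) and the pair's transcriptome-wide `upperQ`
quantile (default 0.975); down-regulation mirrors this with `1/fcMin` and
the 0.025 quantile. The dual criterion prevents both trivially-large
quantile calls in quiet transcriptomes and sub-2-fold "extremes" in noisy
ones. A gene is a DE call if extreme in at least one pair — appropriate
for a heterogeneous disease in which individual patients may dysregulate
different module members.

## 4. Variant burden

"Rare" is defined strictly as *absent from the reference panel* (missing
reference allele frequency), not as a low-frequency cutoff.
`afCaseVsReference` reconstructs reference allele counts as
`round(ref_af * ref_an)` with `ref_an` defaulting to 5008 haplotypes (a
1000-Genomes-scale panel) when the table does not carry its own; each
panel-present variant gets a two-sided Fisher test (two-sided because a
variant can be enriched or depleted in cases), BH within the variant
family, and genes are reported when any variant passes the FDR target
(default 0.1). Silent variants travel through every test untouched as a
negative-control class.

**Reciprocal regression.** With case and control cohorts,
`reciprocalRegressionOutliers` fits OLS in both directions (case AF on
control AF, control AF on case AF), models each direction's residuals
with a maximum-likelihood location-scale t-distribution (heavy tails are
expected from binomial sampling at low frequencies), and flags residuals
beyond the fitted $1 - tail$ quantile (default tail 0.05). In the
control-on-case direction the residual is *negated* before flagging so
that both directions point at case excess: a case-enriched variant sits
above the line in one regression and below it in the other, and a literal
upper tail in both raw directions would flag case excess in one direction
and control excess in the other, doubling the null rate and answering a
different question. The union over directions is reported with direction
labels, so the intersection (or the raw-tail reading) can be recovered.
The t fit is a small explicit optimization over (location, log scale, log
df) with Nelder–Mead from median/MAD starts — self-contained, with the
likelihood and failure modes under the package's control.

**Rank curve.** `afDifferenceRankCurve` orders variants by decreasing
|case AF − control AF| (ties broken by variant id for determinism) and
measures the fraction of top-$k$ variants on candidate genes over a grid
of $k$ (default: ten cuts spanning the top 2–20% of variants). The
statistic is the curve's mean; its null resamples candidate-sized gene
sets from the module. Scoring is variant-level by default with a
gene-level option, since a gene with many shifted variants is genuinely
stronger evidence at variant level.

**Coreness burden.** `corenessBurdenProfile` bins module genes by
coreness, tests each layer by hypergeometric enrichment *and* depletion
(universe = module), and summarizes the layer profile with
$S = (f_{top} + f_{bottom}) - 2 f_{middle}$, a contrast that is positive
for U-shaped profiles (burden at the center and periphery, depletion in
intermediate layers) and 0 in expectation under uniform burden. $S$ is a
declared, seeded statistic reported with its full permutation null.
Default bins are the fixed layers {1}, {2}, {3–5}, {6–9}, {≥10}; when a
module's coreness range is too narrow to populate three fixed layers, the
pipeline switches to data-driven tertile layers (`corenessTertileBins`),
and empty bins are excluded from $S$ rather than imputed.

## 5. Synthetic data: what it emulates, and what it does not

Each generator is a pure function of its parameters and seed (identical
outputs on regeneration), and serializes its ground truth as JSON.

* `genModularNetwork` — stochastic block model. Defaults (10 blocks of 30,
  `pIn = 0.3`, `pOut = 0.005`) give a strongly modular desk-scale network
  whose first-level recovery is checkable by adjusted Rand index.
* `genGeneAnnotation` — log-normal CDS lengths (median ≈ 1500 bp,
  `sdlog = 0.7`) and Beta(26, 24) GC content (centered near 0.52, the
  human coding average); disease genes sampled with probability
  ∝ `cds_length^log2(confoundFactor)`, so `confoundFactor = 2` plants
  exactly the long-gene ascertainment bias the matched background must
  neutralize.
* `genExpressionMatrix` — log-normal noise (multiplicative error matches
  FPKM/intensity behavior and guarantees positivity) around a `log(5)`
  baseline; group 1 gains `effectSize` (log scale, default 2) in the T1
  samples only, while the optional group 2 is elevated everywhere with a
  modest dip in T1 — the tissue-specific vs ubiquitous contrast of brain
  expression atlases.
* `genVariantTable` — per-gene Poisson variant counts; reference allele
  frequencies from Beta(0.2, 2) truncated to [0.001, 0.5], a
  site-frequency-spectrum-like skew without demographic modeling;
  panel-absent ("rare") variants segregate at a latent 0.002 frequency;
  case/control allele counts are binomial, with planted genes' case
  counts shifted by `afShift` on nonsynonymous variants. A planted gene
  is guaranteed one nonsynonymous variant, and when a frequency shift is
  requested that variant is panel-present — an unobservable planted
  signal would be a property of the scene, not of the method under test.
  Cohort defaults (1010/982 case/control alleles, 5008 reference
  haplotypes) are exome-cohort scale.
* `genPairedCaseControlExpression` — six matched pairs by default;
  planted genes multiplied or divided by `foldChange` (default 3) in the
  case member.
* `genSyntheticScene` composes all layers coherently around one planted
  module (its disease enrichment, expression split, burden genes and DE
  genes), with per-layer seeds derived from one scene seed.

These generators emulate *shapes and effect structures*, not biology:
there is no linkage disequilibrium, no population stratification, no
probe-level artifacts, no correlated expression beyond the planted
blocks, and network degrees within a block are homogeneous (no hubs
inside modules). Passing recovery tests therefore demonstrates that the
statistics detect what they claim under their stated models — not that
real curated data would behave as cleanly.

## 6. Pipeline, seeding and reproducibility

`runPipeline` executes stages in dependency order (simulate →
modularize → null test → enrich → match → dichotomize → specificity →
DE → burden → outliers), writing each stage's tables before the next
starts and aborting with a stage-labeled error on failure. Configuration
is flat `key = value` text under `[sections]`; unknown sections or keys
are rejected so typos cannot silently fall back to defaults. One global
seed fans out to per-stage seeds through a fixed multiplicative
congruential derivation (`deriveSeed`), so changing one stage's seed
leaves the other stages' outputs untouched, and a re-run with an
identical config is byte-identical in its JSON summary (numbers are
serialized at fixed precision; no timestamps enter the report).

Problem sizes in the test suite and acceptance script are desk-scale by
design — networks of ~300 nodes, 200-replicate calibration loops with
199 permutations each, 20-seed recovery panels — chosen so the full suite
completes in minutes while every statistic still has room to show
calibration (the discrete permutation statistics need enough support for
their p-values to be near-uniform; the scenario sizes used give the
overlap and fraction statistics tens of achievable values).

## 7. Known limitations

* First-level modularity maximization inherits the resolution limit of
  modularity; very small complexes surface only through
  `subclusterModule`.
* The matched background balances the covariates it is given; unmeasured
  confounders (e.g. expression level, study attention) pass through.
* The reciprocal-regression outlier model assumes a single homogeneous
  cohort; population structure would inflate the tails in both
  directions.
* The per-variant reference comparison reconstructs panel counts from
  rounded frequencies; for panels reporting exact counts, supplying
  `ref_an` per variant removes the rounding error.
* Empirical p-values are bounded below by `1/(1 + nPerm)`; claims beyond
  that resolution require more permutations, not a different convention.
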