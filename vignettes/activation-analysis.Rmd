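---
title: "Analysing neuronal activation states from single-nucleus RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing neuronal activation states from single-nucleus RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snactivity)
library(dplyr)
```

## The problem

Single-nucleus RNA-seq (snRNA-seq) of dentate granule cells can read out
the transcriptional response to neuronal activity: immediate early genes
(IEGs) such as *Fos*, *Arc* and *Egr1* are induced within an hour of an
activating experience, and nuclei can be sorted by FOS protein stain
into putatively activated (FOS+) and resting (FOS−) groups. The stain is
a noisy, binary snapshot of a continuous process, so the analysis has to
do several things at once: exclude failed libraries, quantify per-group
detection of marker genes, test differential expression between the
stain groups, order nuclei along a continuous activation trajectory, and
characterise nuclei whose protein stain and transcriptome disagree
("pseudo-FOS+": FOS protein present, transcriptome still resting).

`snactivity` implements that pipeline end to end, together with two side
analyses — promoter-normalized retrotransposon expression from
template-switch-oligo (TSO) adjacency, and parent-weighted GO similarity
networks — and a synthetic-data generator that emulates the statistical
structure of such a study so every stage is testable without any
external download.

## Quality control

Three per-sample criteria, applied in one pass by `apply_qc()`:

* **Mapped reads.** A nucleus passes iff its uniquely mapped read count
  is strictly greater than 50,000 (`qc_reads()`).
* **ERCC spike-in correlation.** Pearson correlation of
  log2(observed TPM + 1) against log2(expected concentration), tested
  one-sided for *positive* association at α = 0.05 via the t transform
  on n − 2 df (`qc_ercc_correlation()`). One-sided is a deliberate
  choice: an anticorrelated spike panel is evidence of failure, never of
  quality. Fewer than three detected spikes, or zero variance, is an
  automatic fail with the reason recorded.
* **Detected genes.** A nucleus needs at least
  `mean − 2 × SD` detected genes (TPM > 1), where mean and sample SD
  are computed once on the full input batch and frozen in the report.
  The boundary is inclusive (`>=`) so that a zero-variance batch is not
  vacuously emptied; the threshold is not recomputed after removals,
  matching a single filtering pass.

Detection everywhere in the package means TPM **strictly greater** than
the threshold; a gene at exactly 1 TPM is not detected.

## Detection statistics and power

`prop_test_yates()` wraps the 2×2 chi-square test of equal proportions
with continuity correction (each cell contributes
$(\max(0, |O-E| - \tfrac12))^2 / E$; p is the upper χ²₁ tail). A table
with a zero margin is reported as p = 1 with a degenerate flag.
`hypergeom_enrichment()` gives the exact upper-tail hypergeometric p for
target-set overlaps; the universe size is always an explicit argument
because no default is defensible.

`min_sample_size()` reproduces an a-priori power analysis for a
two-sided two-sample t-test using the exact noncentral-t power
$1 - F_{\nu,\delta}(t_{1-\alpha/2}) + F_{\nu,\delta}(-t_{1-\alpha/2})$
with $\delta = d / \sqrt{1/n_1 + 1/n_2}$ and $\nu = n_1 + n_2 - 2$,
searching the smallest $n_1$ with $n_2 = \lceil \text{ratio} \cdot n_1
\rceil$. The normal approximation is deliberately avoided: at
d = 1, α = 0.05, power 0.95, ratio 1.14 the exact search returns
(26, 30) and the approximation misses that boundary.

## Synthetic pooling

`synthetic_pool_overlap()` asks how much of a bulk profile is recovered
by pooling single nuclei: for each pool size it draws up to 25
*distinct* subsets (all of them when fewer exist; full enumeration is
used whenever the number of subsets is within 10× the target, rejection
sampling on canonical keys otherwise), calls a gene pool-detected when
TPM > 0 in at least one member, and reports the mean and SD of the
overlap with the bulk-detected set (bulk TPM > 1). The published
"percent overlap" phrasing is ambiguous about its denominator, so both
conventions are available (`denominator = "bulk"` or `"union"`); bulk is
the default. The 2×2 detection table at the full pool is tested with
`fisher_exact_2x2()` (minimum-likelihood two-sided rule) and the pooled
mean profile is correlated with bulk on the log2(TPM+1) scale.

## Differential expression

The two-group test is a negative-binomial conditional exact test on
expected counts, assembled from explicit, individually tested parts:

1. **Size factors** (`size_factors()`): median of ratios to the
   geometric-mean reference over genes nonzero in every sample,
   renormalized to geometric mean 1; total-count scaling is the fallback
   when no such gene exists.
2. **Equalization**: counts are divided by their size factor and rounded
   half-up, so both groups live on a common effective library size.
   Expected counts are kept unrounded everywhere else.
3. **Dispersion** (`estimate_dispersion()`): per-gene method-of-moments
   $\hat\varphi_g = \max(0, (s^2 - \bar m)/\bar m^2)$ with the pooled
   within-group variance; the common dispersion is the median over genes
   with mean > 1; per-gene values are shrunk with a prior weight of
   W = 10 samples, $\varphi_g = (n\hat\varphi_g + W\varphi_c)/(n + W)$.
   W = 10 is a moderate-shrinkage default, configurable.
4. **Exact test** (`nb_exact_test()`): with group sums
   $S_A \sim \mathrm{NB}(n_A/\varphi,\; n_A\mu)$ and likewise for $S_B$,
   the law of $S_A$ given $S = S_A + S_B$ is beta-binomial
   $(S,\; n_A/\varphi,\; n_B/\varphi)$, degenerating to
   Binomial$(S, n_A/(n_A+n_B))$ at $\varphi = 0$. The two-sided p sums
   all conditional outcomes no more probable than the observed one
   (ties at relative 1e−7, the base-R `binom.test` convention, so the
   Poisson limit matches it to numerical precision).
5. **FDR**: Benjamini–Hochberg (`bh_adjust()`). An empirical-null local
   FDR was considered and rejected: its null fitting is
   under-determined, while BH is fully specified and deterministic.

`run_de()` chains these, optionally excluding flagged pseudo-FOS+
nuclei, and returns a tibble sorted by q. On null simulations (36 vs 43
samples, φ ∈ {0, 0.3}, 2,000 genes) the raw false-positive rate at 0.05
stays within [0.03, 0.07]; the test suite asserts this.

## Pseudotemporal ordering

The ordering is supervised and deliberately simple:

1. **Gene filter**: genes with DE adjusted p < 0.01 (strict).
2. **Embedding** (`reduce_ica()`): genes are z-scored (so high
   expressors cannot dominate), samples are PCA-whitened to 2
   components, and a fixed-point ICA (symmetric FastICA, tanh contrast)
   estimates the unmixing. Coordinates are reported as projections of
   the PCA scores onto the unit-normalized estimated mixing directions.
   This equals the ICA rotation when both components carry real
   structure, and degrades gracefully to the dominant principal
   direction when the data are effectively one-dimensional — on the
   whitened unit-variance scale a pure-noise component would carry the
   same geometric weight as the activation axis and the downstream tree
   would degenerate. Components are ordered by the F statistic of their
   stain association and oriented so the FOS+ mean is positive.
3. **Ordering** (`build_mst_order()`): Euclidean minimum spanning tree
   (Kruskal; ties broken lexicographically on sample-id pairs for
   determinism), main trajectory = the maximum-weight leaf-to-leaf path
   (tree diameter), root = the endpoint with lower mean expression of an
   IEG marker panel so pseudotime increases with activation, pseudotime
   = cumulative path length normalized to [0, 1]. Off-path samples
   attach at their nearest tree node on the path and inherit its
   pseudotime.
4. **Clusters** (`assign_clusters()`): remove the k − 1 longest tree
   edges (k = 5 by default, configurable); components are clusters,
   labelled C1..Ck by ascending mean pseudotime.
5. **Pseudo-FOS+** (`flag_pseudo_positive()`): a nucleus is flagged when
   it stains FOS+ but sits in a cluster whose members are more than 50%
   FOS−. The published account assigns these nuclei visually; the
   majority rule is a defined, testable proxy.

This is a re-specification of the ICA+MST ordering idea, not a wrapper
around any existing trajectory package; numeric agreement with other
implementations is a non-goal. Robustness is assessed by
`loo_robustness()`, which repeats the embedding and ordering with each
sample left out and reports |Spearman ρ| against the full ordering on
the shared samples (the absolute value absorbs orientation flips). The
supervised gene set is computed once on the full cohort and held fixed
across the leave-one-out repeats: the procedure being stress-tested is
the *ordering*, and re-running the DE filter per permutation would
change the question being asked.

Per-gene trends are tested by `gene_pseudotime_regression()` (simple
linear regression of log2(TPM+1) on pseudotime over main-trajectory
samples, F-test, BH) and clusters are characterised by
`cluster_vs_rest_regression()` (indicator regression, equivalent to a
pooled-variance two-sample test).

## Retrotransposon quantification

Retrotransposon sequence in reads can come from Pol-II transcripts that
merely contain a repeat, or from transcription initiated at the
element's own promoter. The conservative signal for the latter is a read
in which the TSO is *directly adjacent to the start* of the repeat
consensus. `scan_tso_adjacent()` implements that rule: exact
forward-orientation TSO match, then the following `prefix_len = 20`
bases must match a consensus window beginning within the first
`start_window = 5` bases with at most `max_mismatch = 2` mismatches.
Multi-element hits go to the element with the fewest mismatches
(alphabetical tie-break, flagged). The tolerances are declared defaults,
not inferred values, and all three are arguments. The TSO itself is a
required parameter — it is a protocol reagent, not a constant — and the
read generator uses a documented 30-nt example oligo.
`promoter_normalized_counts()` divides TSO-adjacent counts by total
per-consensus counts; totals come from an external aligner in real use,
or from the package's naive exact-seed counter for synthetic fixtures.

## GO similarity networks

`build_go_network()` builds the binary gene × term annotation matrix,
weights each term by its number of parents, and connects gene pairs
whose weighted cosine similarity
$\sum_j w_j x_j y_j / \sqrt{\sum_j w_j x_j^2 \sum_j w_j y_j^2}$
is strictly above 0.5; the exported edge distance is 1 − similarity.
Two genuinely open conventions are parameterized rather than guessed:
"number of parents" defaults to *direct* parents (the literal reading)
with `"ancestors"` (transitive count) available, and weights enter the
inner products linearly (w, not w²). Cycles in the parent table are an
error. Edge lists export as TSV and GraphML; drawing is out of scope.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design so the pipeline can be
tested against known truth:

* Two stain groups of 36 FOS+ and 43 FOS− nuclei by default.
* A latent activation pseudotime $t \in [0,1]$ per nucleus drawn from a
  two-component Beta mixture (Beta(2,8) and Beta(8,2), weights matching
  the group sizes): a resting and an activated state bridged by
  intermediate nuclei. This bimodal-with-bridge shape is the structure
  the study describes — two expression groups whose junction is
  populated by transitional nuclei — and is what makes the MST
  trajectory and the cluster analysis meaningful on synthetic data.
* 8,000 genes with log-normal baseline means (meanlog 1, sdlog 1.6); a
  500-gene activation program amplified by $\text{effect}^t$ with
  effect = 4 at full activation, so the program is log-linear in t.
* Negative-binomial counts (φ = 0.3) thinned by logistic dropout on the
  log mean (midpoint −2.5, slope 0.8); TPM is computed from counts by
  per-sample scaling to 10⁶ (no gene-length modelling — lengths add
  nothing testable here).
* FOS+ stain assigned to the highest-t nuclei, then each mid-range FOS−
  nucleus relabelled FOS+ with probability 0.1: the pseudo-FOS+
  analogue (protein on, transcriptome not yet responded).
* Library sizes log-normal around 120,000 mapped reads (CV 0.15), a
  realistic uniquely-mapped depth comfortably above the 50,000-read QC
  bound.

The meanlog/sdlog/dropout defaults were calibrated once so a nucleus
detects roughly 6,000 of the 8,000 genes at TPM > 1, matching the scale
of detected-gene counts such studies report; they were then frozen.
`simulate_ercc()` adds log-spaced spike concentrations over five orders
of magnitude with log-normal measurement noise and optional per-sample
shuffling (QC-failure analogue); `simulate_te_reads()` emits three read
classes (TSO+start, TSO+internal, consensus-only) with exact truth
tables.

What the generator does *not* emulate: gene–gene correlation beyond the
shared activation program, batch and amplification-chemistry effects,
gene-length bias, UMI structure, sequencing errors, and any cell-type
mixture. Passing tests therefore demonstrate correctness of the
statistics and the recoverability of a planted activation continuum —
not robustness to every artefact of real snRNA-seq data.

## Numerical choices and degenerate inputs

* Strict inequalities wherever a threshold is stated as "greater than"
  (detection, reads, DE filter, network edges); the single documented
  exception is the inclusive gene-count QC boundary.
* MST and cluster ties break lexicographically on sample-id pairs;
  subset uniqueness in pooling uses canonical sorted keys.
* Zero-margin 2×2 tables: p = 1 (flagged). Zero-variance correlations:
  explicit failure, never NaN. All-zero genes: dispersion falls back to
  the common value; constant genes regress to p = 1. Empty cohorts,
  single-sample batches and rank-deficient embeddings raise informative
  errors.
* Exact-test tail sums are clamped to 1; probability ties are matched at
  relative 1e−7.

## Problem sizes

The bundled tests exercise the full default cohort (8,000 genes × 79
nuclei) for the DE and pseudotime stages, ten seeded cohorts for the
trajectory-recovery check, 2,000-gene null matrices for the type-I-error
check, and small enumerable fixtures wherever an exact brute-force
oracle is asserted. These sizes were chosen so that every statistical
claim is tested at the cohort scale the generator defaults define while
the whole suite stays quick to run.
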