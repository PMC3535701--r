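---
title: "Differential combinatorial regulatory network analysis with comboreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential combinatorial regulatory network analysis with comboreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboreg)
```

## The problem

In many cancers the transition to a metastatic phenotype is accompanied not
only by changes in which genes are expressed, but by changes in *who
regulates whom*. Transcription factors (TFs) activate or repress genes and
microRNAs; microRNAs (miRNAs) post-transcriptionally repress genes and TFs.
`comboreg` implements a pipeline for comparing such combinatorial
TF–miRNA–gene regulatory networks between two phenotype groups of the same
patient cohort — here labelled `NM` (non-metastatic) and `M` (metastatic) —
and for turning the parts of the network that differ into a classifier of
the phenotype.

The pipeline has five stages:

1. **Preprocessing** — quantile normalization across samples and removal of
   the least variable rows.
2. **Candidate pairs** — sequence-based regulator→target predictions from
   several sources are reduced to a consensus set, typed by the node
   annotation, and pruned by an expression-correlation filter with an
   empirical null.
3. **Network inference** — per phenotype, Context Likelihood of Relatedness
   (CLR) scoring of the mutual-information (MI) matrix over the candidate
   node set; candidate pairs whose CLR score reaches a cutoff become
   directed, weighted edges.
4. **Differential modules** — edges whose weights barely differ between the
   two networks are discarded; each remaining regulator with more than one
   first-layer target defines a module, tested for phenotype association
   with a permutation global ANCOVA and ranked.
5. **Classification** — recursive-partitioning (CART) trees over module
   member expression, accumulated over the top-ranked modules, evaluated by
   leave-one-out cross-validation (LOOCV) with accuracy (ACC) and Matthews
   correlation coefficient (MCC); a t-test + mRMR gene-list classifier is
   the single-gene counterpart for comparison.

## Models and statistics

### Correlation pre-filter

For every candidate pair the absolute Spearman correlation across all
samples is compared with an empirical null: `n_reps` (default 100) draws of
`n_pairs` random distinct node pairs are pooled and the pair must exceed
the pooled 95th percentile (`null_threshold()`, `filter_pairs()`). Pooling
all draws uses the full null distribution; the per-draw-mean variant is a
coarser summary of the same null, and with 100 × `n_pairs` values the
pooled quantile is far more stable. Retention of pure-noise pairs is
therefore close to 1 − q by construction, which the test suite checks
within binomial error.

### MI and CLR

MI between two expression vectors is estimated by discretization
(`mi_config()`): equal-width binning with ⌊√n⌋ bins and natural logarithm
by default — the customary defaults of discrete MI estimators in
transcriptional network inference; equal-frequency binning and log base 2
are available. For each node *i* the CLR background is the mean μᵢ and
standard deviation σᵢ of its off-diagonal MI row; the edge score is

  score(i, j) = √(zᵢ(j)² + zⱼ(i)²),  zᵢ(j) = max(0, (MIᵢⱼ − μᵢ)/σᵢ).

The MI/CLR matrices are computed over **all** nodes of the retained
candidate set, so each node's background reflects the whole candidate
context, and scores are comparable across pairs. Edge direction comes
solely from the prior pair's orientation (CLR itself is symmetric); the
default edge-weight cutoff is 1, with ties at the cutoff kept (only
strictly smaller weights are removed).

### Differential modules and the permutation global ANCOVA

Over the union of the two networks' edges, |w_NM − w_M| is computed with
missing edges counted as weight 0, and the lowest 25% are removed from both
networks as non-discriminative. A module is one regulator plus all of its
remaining first-layer targets (at least two), named `Regulator_Status` with
`-` replaced by `_` (so `hsa-miR-16` in the M network heads
`hsa_miR_16_M`).

Each module's node set (regulator **and** targets — the published module
tables list both as module members) is tested with a pooled two-group
ANCOVA statistic

  F = [Σ_g (RSS_red,g − RSS_full,g)/G] / [Σ_g RSS_full,g/(G(n−2))],

which for a single node reduces exactly to the squared pooled t statistic
(verified numerically in the tests). Significance is assessed by random
label permutations with the +1 correction, p = (1 + #{F* ≥ F})/(1 + P).
One permutation set is shared across all modules, as is standard for
permutation gene-set tests; this makes large P cheap. The default in
`rank_modules()` is P = 50 000 because the Benjamini–Hochberg gate at
α = 0.001 needs resolution: with m modules the smallest attainable
adjusted p is m/(P + 1), so P must comfortably exceed m/α or no module can
ever pass. (`global_ancova()` on its own defaults to P = 1000, which is
ample for a single test at conventional levels.) Modules with BH-adjusted
p < 0.001 are kept, sorted by raw p (ties by name), and ranked.

### Classification

CART trees are grown by Gini impurity with the conventional defaults
(minsplit 20, minbucket 7, cp 0.01, maxdepth 30; `tree_params()`). For the
cumulative-module classifier, one tree per module is fitted per LOOCV fold
on the module's member expression; per-class probabilities are summed over
the top-k modules and the larger sum wins, with ties going to `NM`, the
majority class. Because each module's held-out probabilities do not depend
on k, `cumulative_module_scan()` evaluates every prefix k = 1..k_max from a
single set of fitted trees; the classifier size is then chosen at the peak
of the accuracy curve, mirroring how the module-accumulation procedure is
used in practice. Module selection and ranking are computed once on the
full data and held fixed across folds — this reproduces the original
procedure and carries its optimistic bias, which should be kept in mind
when reading absolute LOOCV numbers.

The gene-list counterpart (`genelist_rank()`, `genelist_loocv()`) gates
nodes by a two-sided pooled-variance t-test at BH-adjusted p < 0.001 and
ranks survivors by minimum-redundancy–maximum-relevance (mRMR, MID form:
MI relevance to the label minus mean MI redundancy with the selected set,
same discretization as the network MI estimator), then fits a single tree
over the top genes, size-matched to the module classifier.

### Enrichment

`fisher_overlap()` is the one-sided Fisher exact (hypergeometric
upper-tail) test. Module enrichment tests the module's first-layer target
genes only (the regulator is excluded), against each gene set, with
unadjusted p compared to α = 0.05 by default — matching the convention of
the published module-pathway table, whose p-values are raw; a BH-adjusted
gate is available via `adjust = TRUE`. The default universe is the
expressed gene set; it is an explicit argument because enrichment p-values
are sensitive to that choice.

## The synthetic-data generator

Real inputs of this kind (paired mRNA/miRNA microarrays plus several
target-prediction databases) cannot be redistributed or downloaded at test
time, so `synth_config()`/`simulate_study()` generate studies with planted
structure:

* A directed network over `n_tf = 10` TFs, `n_mirna = 10` miRNAs and
  `n_gene = 200` genes; each regulator receives 2 + Poisson(2) targets
  drawn under the five legal edge types. Each edge is shared between the
  two conditions with probability `common_fraction = 0.5`, otherwise it is
  specific to one condition.
* Linear-Gaussian expression: source nodes are i.i.d. N(0, 1); a target is
  the effect-weighted sum of its in-condition parents plus N(0, noise_sd²)
  noise, `noise_sd = 0.5`. Effect magnitudes are
  `effect_min + |N(0, effect_sd)|` with `effect_min = 1`, so every effect
  satisfies |effect| ≥ 2·noise_sd — a strong-signal regime. miRNA effects
  are always negative (repression); TF signs are Rademacher. The
  linear-Gaussian choice is the simplest model satisfying the monotone
  dependence that both Spearman and MI detect.
* **Differential regulator activity**: a regulator with condition-specific
  targets receives a mean shift (`activity_shift = 1`) in that condition,
  which its targets inherit through their effects. This couples re-wiring
  to differential expression, as in real tumours where a regulatory
  program's activation is what creates condition-specific edges. Without
  it the two conditions would differ only in covariance structure, group
  means would be identical, and no mean-based module test or classifier
  could succeed; setting `activity_shift = 0` recovers that pure
  re-wiring model.
* Sample sizes default to 60 NM / 20 M, the same 3:1 imbalance as typical
  metastasis cohorts. Candidate priors emulate `n_sources = 3` databases,
  each reporting a true edge with probability 0.85 and a legal non-edge
  with probability 0.05, so the two-source consensus keeps ~90% of true
  edges and a thin layer of false positives.
* One global seed drives a fixed per-operation seed sequence, so the
  network, the expression matrix and the priors are each independently
  reproducible.

What the generator does **not** emulate: probe-level artifacts, batch
effects, platform-specific intensity distributions, correlated
measurement noise, or realistic miRNA/mRNA abundance scales. Passing the
recovery tests therefore demonstrates internal correctness of the pipeline
under its own assumptions, not performance on any real cohort.

Regulator→regulator edges can in principle form cycles; values are then
generated in one pass over nodes in id order after a topological sort
fails, a documented contract rather than a fixed point.

## Numerical and design choices

* **Variance filter**: removes exactly ⌊frac·n⌋ rows with the smallest
  standard deviation, computed across *all* samples of the combined
  profile (the simplest reading when the two groups share one matrix);
  ties break lexicographically by node id.
* **Quantile normalization** delegates to `limma::normalizeQuantiles`
  (`ties = TRUE`), the standard implementation.
* **Strictness conventions**: the correlation filter keeps pairs *strictly
  above* the null quantile ("higher than"); the CLR cutoff keeps weights
  *at or above* 1 (only "below" is removed); the significance gate is
  adjusted p *strictly below* α.
* **Degenerate inputs**: constant vectors have Spearman correlation and MI
  defined as 0 (with a warning for the correlation); a constant CLR row
  (σ = 0) contributes zero z-scores; an all-constant module has F = 0,
  p = 1; a single-class training response yields a stump predicting that
  class with probability 1; an MCC denominator factor of 0 gives MCC = 0.
* **Average-target increase rates** (network comparison) restrict the
  denominator to regulators with at least one target of the given type —
  otherwise the denominator set is ambiguous — and are undefined (NA) when
  the combination is absent from the NM network.
* **Betweenness** is computed on the directed graph, unnormalized; ranked
  hub/bottleneck lists break ties by node id.
* **Consensus rule**: miRNA→gene and miRNA→TF candidate pairs are treated
  identically (both pass through the same ≥2-source consensus); TF-headed
  pairs are consumed as given.
* **Probability aggregation**: summing per-module probabilities and taking
  the larger total is equivalent to averaging for a fixed module count;
  sum is used.

## Problem sizes used by the tests and the acceptance script

The suite exercises the full pipeline at the default study size
(220 nodes, 80 samples) over 20 seeds for recovery metrics, 1000 null
simulations (n = 40, 5-node modules, 199 permutations each) for ANCOVA
type-I calibration, and ~2400 probe pairs for the noise-retention check;
brute-force oracle comparisons run on instances small enough to enumerate
(≤ 6-node CLR matrices, ≤ 25-gene universes, ≤ 8-node digraphs, 10-sample
trees). The label-permutation symmetry check uses equal group sizes
(40/40) because with unequal groups the larger group's network is
systematically denser — a sample-size artifact that would confound the
exchangeability the check relies on.

## Worked example

```{r example, eval = FALSE}
library(comboreg)

cfg <- pipeline_config(seed = 7)
summary <- run_pipeline(cfg, "run7")
str(summary$classifier)
#> List of 4
#>  $ k         : int 9
#>  $ acc       : num 0.975
#>  $ mcc       : num 0.937
#>  $ n_features: int 24
```

Every intermediate (expression, priors, kept pairs, both networks, module
table, classifier scan) is persisted under the run directory, and a rerun
with the same config and seed is byte-identical.

## Known limitations

* The module significance gate inherits the resolution limits of
  permutation p-values; α far below 1/P is unreachable by construction.
* Module pre-ranking on the full data biases LOOCV estimates upward; a
  nested re-selection per fold would be honest but is not what the
  original procedure does.
* The discrete MI estimator is biased upward for small samples; CLR's
  per-node standardization absorbs most of this, but MI values themselves
  should not be compared across sample sizes.
* Real-data network sizes and real-cohort classifier performance are not
  reproducible from synthetic studies and are out of scope here.
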