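---
title: "Recursive cluster elimination with intra-cluster feature elimination: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive cluster elimination with intra-cluster feature elimination: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rceife)
```

## The problem

Omics classification tasks — tumour versus normal from expression arrays,
disease versus control from miRNA counts, methylation beta values or
metagenomic abundances — routinely present a few dozen to a few hundred
samples against tens of thousands of features. Most features are irrelevant,
and the relevant ones arrive in correlated groups (co-expressed genes,
co-methylated CpGs, co-abundant taxa). Feature selection that scores
features one at a time ignores that group structure; selection that operates
on *clusters* of correlated features can discard whole redundant groups at
once and keep a compact, interpretable panel.

`rceife` implements such a group-wise selector. It iterates four steps along
a user-supplied, strictly decreasing schedule of cluster counts
$M = (M_1 > M_2 > \dots > M_K)$:

1. **Grouping.** The currently active features are clustered into $M_i$
   groups by k-means, each feature represented as its vector of values
   across the training samples.
2. **Scoring.** Each cluster receives the mean held-out accuracy of a
   classifier trained on that cluster's features alone, over $t$
   independent stratified 70/30 subsamples of the training data
   (Monte-Carlo cross-validation).
3. **Cluster elimination.** The $M_i - M_{i+1}$ lowest-scoring clusters are
   dropped, features and all.
4. **Intra-cluster feature elimination.** Inside every surviving cluster
   with more than five features, the bottom $f\%$ of features by learner
   importance are removed. The pooled survivors become the active set, a
   fresh model is fitted on the training side, and the full metric set is
   recorded on the untouched held-out test side.

Before the loop, the data are optionally balanced by undersampling the
majority class, split 90/10 with stratification, and screened to the 1,000
smallest two-sided t-test p-values. The whole run is repeated (100 times in
the reference protocol) with fresh undersampling and splits, and every
metric is reported as a mean ± sd over the repetitions in which it was
defined. Features are finally ranked by *survival*: the number of
elimination levels they persisted through, summed over repetitions.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `schedule` | 100, 90, 70, 50, 30, 20, 10, 5, 2 | cluster counts per level; the head is capped at the filtered feature count |
| `train_fraction` | 0.9 | outer stratified split; the 10% side is only ever used for evaluation |
| `n_top` | 1000 | features kept by the univariate t-test screen |
| `t` | 10 | inner stratified 70/30 subsamples behind every cluster score |
| `f` | 10 (%) | intra-cluster removal rate; 0 disables pruning |
| `min_cluster_size_for_ife` | 5 | clusters at most this size are never pruned |
| `learner` | random forest (100 trees) | used for scoring, importance and modeling; a linear SVM variant is available |
| `balance` | on | undersample the majority class before splitting |

The default schedule extends the three-level illustration (100, 90, 70)
down to the two-cluster readout used for all reported numbers; intermediate
levels were chosen to roughly halve the cluster count per step.

## Design choices where the procedure was open

**Inner "cross validation".** The scoring step is described both as
stratified random 70/30 partitioning repeated $t$ times and as "$t$-fold
cross validation". The two are incompatible — disjoint 10 folds cannot have
a 70/30 ratio — so `rceife` implements the literal algorithm: $t$
independent stratified 70/30 subsamples, averaged. This is Monte-Carlo CV;
the disjoint-fold alternative is deliberately not offered.

**t-test variant.** Only a "two-sided t-test" is specified. The default is
Welch's unequal-variance statistic, the safer choice for heteroscedastic
omics data; a pooled-variance flag exists. Features constant in both classes
get $p = 1$ so they sort last deterministically rather than erroring.

**Order of balancing and splitting.** Undersampling is applied once per
repetition *before* the outer split, so both the training and the test side
stay balanced and chance accuracy is 0.5 on both. The alternative
(balancing only the training side) would leave test metrics dominated by
the majority class.

**Stratification of the outer split.** The split is described only as
"random"; `rceife` stratifies it per class (floor of the fraction to train,
remainder to test, with a guard that moves one sample back if a class's
test side would be empty) so AUC is always defined.

**Standardization before k-means.** Each feature is z-scored across
training samples before clustering (a flag disables it). Without it,
Euclidean k-means on raw expression groups features by absolute magnitude
rather than by co-variation, which defeats the purpose of redundancy-aware
elimination. Zero-variance features — possible after undersampling — map to
zero vectors rather than erroring.

**Rounding of the $f\%$ rule.** For an eligible cluster of $n > 5$
features, `n_remove = max(1, floor(f/100 * n))`. The bare floor would
remove nothing from clusters of 6–9 features at $f = 10$ and stall the
reduction; the `max(1, ·)` guarantees progress while `n_remove ≤ n − 1`
keeps every surviving cluster non-empty.

**Tie rules.** All ties break deterministically: cluster elimination sorts
by (score descending, cluster id ascending), so among tied clusters the
largest id is dropped first; intra-cluster removal drops later feature ids
first among tied importances; the survival ranking breaks ties by feature
id ascending. Reproducibility was preferred over randomized tie-breaking.

**Seeds.** Every stochastic step draws a seed derived from the master seed
and its integer context (repetition, iteration, cluster, split) through a
fixed congruential fold modulo $2^{31}-1$. Two runs with the same master
seed are bit-identical; the manifest records the derived seeds.

**Undefined metrics.** A metric whose denominator is zero (no predicted
positives, say) is recorded as missing, excluded from repetition means, and
the count of defined repetitions is reported. Averaging zeros instead would
bias the summaries downward in exactly the imbalanced settings the method
targets.

## What the synthetic generator emulates — and what it does not

`simulate_blocks()` plants blocks of equicorrelated Gaussian features
(pairwise correlation $\rho$, built as a shared factor plus independent
residuals) with a between-class mean shift expressed in within-class SD
units, on a background of independent Gaussian noise. This reproduces the
two properties the engine exploits: informative features arrive in
correlated groups, and groups carry a class signal. It deliberately does
*not* model heavy tails, count noise, compositionality or zero inflation of
real sequencing data, batch effects, or correlated noise blocks without
signal. Passing the synthetic checks therefore demonstrates that the
machinery is correct and that it recovers block-structured signal at
realistic effect sizes — not that any particular real dataset will reach a
given AUC.

Validation problem sizes: engine-level checks use 60/60 samples with 2,000
features and three planted blocks of 10 informative features at effect 1.5
SD and $\rho = 0.6$, run down the schedule 50, 40, 30, 20, 10, 5, 2 — large
enough that the t-test screen, clustering and both elimination phases all
do real work, small enough that a full run takes seconds on one core.
Repetition counts in tests and in `scripts/acceptance.R` (10–20) are scaled
down from the reference 100; means stabilize well before that at these
sample sizes.

## Degenerate inputs and numerical notes

- `k = 1` puts every feature in one cluster; `k ≥` the active count makes
  every feature a singleton. Empty k-means clusters are dropped, and if the
  effective count falls below the next schedule level, cluster elimination
  is skipped for that step (with a warning) while pruning still runs.
- A schedule head larger than the filtered feature count is capped, with a
  warning, rather than erroring.
- AUC is computed as the Mann–Whitney rank statistic (ties count ½), which
  is exactly the trapezoidal ROC area and needs no threshold sweep.
- Cohen's kappa returns missing when the margin-expected agreement is 1.
- Loading rejects missing values outright, listing the offending cells;
  silent imputation would change scores invisibly. More than two label
  values is an error, not a grouping.

## Known limitations

- Two-class problems only; multiclass labels are rejected at load.
- k-means is the only grouping backend; prior-knowledge groupings
  (pathways, gene sets) are out of scope.
- The survival ranking aggregates across repetitions by a plain sum of
  per-repetition level counts; repetitions are equally weighted.
- Runtime grows roughly with (clusters scored) × $t$ forest fits per
  level; very long schedules on wide matrices are the dominant cost.
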