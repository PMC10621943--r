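---
title: "Stage discrimination and rule mining: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage discrimination and rule mining: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagemine)
```

# The problem

Bulk tumor expression cohorts — FPKM-like sample-by-transcript matrices with
a binary stage label (early = AJCC I–II, late = III–IV) — pose two coupled
questions: which small transcript panel discriminates the stages, and which
transcript co-expression patterns travel with each stage. `stagemine`
answers both with a five-stage workflow: leakage-free nested
cross-validation and normalization, a univariate filter, a genetic wrapper,
multi-classifier evaluation, and association-rule mining with rule
analytics. A seeded synthetic-cohort generator with planted ground truth
makes every stage testable without access to a real cohort.

# Nested cross-validation and per-fold cleaning

`build_nested_folds()` creates 10 outer folds and, within each outer
training set, 5 inner folds (the defaults; both configurable). Outer test
samples never touch any fitted quantity: cleaning masks, normalization
parameters, filter rankings and wrapper fitness all come from training or
inner-training rows only.

Two decisions here were genuinely open:

* **Stratification.** Splits are stratified by stage. With a ~32% minority
  class, unstratified inner folds of ~30 samples would occasionally hold
  almost no late-stage samples, making validation AUC undefined or wildly
  unstable. Per-class remainders are spread across folds so total fold sizes
  also differ by at most one (554 samples → outer test sets of 55 or 56).
* **Constant-feature masks.** A feature is dropped when it is constant on
  the training rows of an inner fold. Within an outer fold the per-inner-fold
  keep-masks are intersected before the filter runs — the conservative
  reading: a feature unusable in any inner partition of that outer fold is
  excluded from all of them.

Two normalizations serve different consumers: z-scoring (sample, n−1, sd)
for filter/wrapper/classification, fit on training rows and applied
unchanged to held-out rows; min–max scaling to [0, 1] for rule mining.
Because rule mining is a descriptive, unsupervised stage applied once to the
final selected-feature matrix, its min–max parameters are fit on all
samples.

# Filter: Welch t-test pooling

For every inner training partition (10 × 5 = 50 at defaults),
`ttest_rank()` computes a per-feature Welch (unequal-variance) t statistic —
group sizes are unequal, so the pooled-variance form would be mis-calibrated
— and `select_top_k()` keeps the 15 smallest p-values. Ordering is fully
deterministic: p ascending, then |t| descending, then feature id. The
candidate pool is the union of all 50 selections with per-feature counts
(`pool_candidates()`); one global pool feeds the wrapper, with per-outer
pooling available behind the `scope` switch.

# Wrapper: binary NSGA-II

Each genome is a bitmask over the candidate pool. Fitness of a genome on an
outer fold trains a classifier on each inner training partition restricted
to the set bits and scores its validation partition by rank-based AUC
(positive class = late). The scalar fitness is

$$\mathrm{eq1} = 1 - \overline{\mathrm{AUC}} + s_{\mathrm{AUC}},$$

the mean and sample standard deviation taken over that outer fold's inner
validation AUCs — rewarding both high and stable validation performance. An
empty genome receives the worst possible value (mean 0, sd 1, eq1 = 2)
instead of an error so the search continues.

Open choices, and how they were resolved:

* **Objectives.** The printed fitness is a scalar, yet the search machinery
  is multi-objective. The default mode minimizes the pair
  (eq1, number of selected features): the explicit parsimony objective is
  what produces compact panels (tens of transcripts from a pool of
  hundreds). `objective_mode = "scalar"` reproduces a single-objective
  degenerate run. Eq1 is the reported fitness either way.
* **Genetic operators.** Unspecified upstream, so standard choices, all
  configurable: binary tournaments on the crowded-comparison order, uniform
  crossover with probability 0.9, per-bit mutation 1/L, initial bit
  probability 0.25 (expected initial subset ≈ pool/4).
* **Fitness classifier.** The contract is `fit(x, y)` / `score(model, x)`
  with higher scores favouring the late stage; anything — including an
  external deep model — plugs in. The default is the linear discriminant
  (`classifier_lda()`): a margin-based linear classifier that fits in
  milliseconds, which matters because a single run needs tens of thousands
  of fits. The linear SVM is provided (`classifier_svm_linear()`) and is the
  headline classifier in the evaluation roster; swapping it into the wrapper
  is one argument.
* **Survival details.** Crowding distance gives boundary points infinity;
  an objective with zero range across a front contributes 0 (avoiding a
  0/0). The last admitted front is truncated by descending crowding with a
  stable index tie-break. Best-of-run is the minimal eq1, ties broken toward
  fewer selected features, then lexicographically earliest feature indices —
  so repeated runs at one seed are bit-identical.

One NSGA-II runs per outer fold (fold *i* seeded `seed + i`);
`finalize_selection()` unions the per-fold best genomes, ordering features
by how many outer folds selected them. How the original study merged its 10
per-fold results is not stated; the union is this package's documented
reading, and the per-fold results are returned alongside it.

# Evaluation

`evaluate_feature_set()` reports, per classifier, the averaged train /
inner-validation / outer-test metrics: accuracy (%), AUC-ROC, per-class F1,
MCC, sensitivity and specificity. Conventions, stated once and used
everywhere: the late stage is positive (Sn is late-stage recall); margin
classifiers threshold at 0 and probabilistic ones at 0.5 (predicted late at
or above threshold); F1 is 0 when its denominator vanishes; MCC is 0 when
any marginal is zero. `zero_fill_projection()` supports external-cohort
validation where only part of the panel is measurable: missing features
become exact zero columns so the fitted feature vector is preserved.

# Rule mining

The selected-feature matrix is min–max scaled, discretized per feature into
equal-frequency tertiles (low/medium/high), and encoded one transaction per
sample with the stage label as one extra item. Frequent itemsets come from
an FP-Growth implementation (prefix tree over support-ordered items,
recursive conditional pattern bases) and rules from scoring every
bipartition of each frequent itemset on exact transaction counts.

* **Tertiles, not equal-width bins.** The binning was unspecified. On
  right-skewed FPKM marginals, equal-width bins on [0, 1] would leave the
  "high" level nearly empty, and no itemset containing it could reach a 0.3
  support floor; equal-frequency tertiles give every level support ≈ 1/3.
  Cuts are made on average ranks, so the assignment is invariant to monotone
  transforms and deterministic under ties.
* **Thresholds are inclusive** (kept when ≥ the threshold, to within a
  1e-9 floating-point tolerance); defaults are min-support 0.3, max
  frequent-itemset length 4 (antecedent plus consequent, consistent with
  3-antecedent → 1-consequent rules), minimum lift 1.1, minimum confidence
  0. The smallest qualifying count is `ceiling(min_support * n)`, computed
  with a guard against representation error.
* **Oracle.** `bruteforce_frequent_itemsets()` enumerates every itemset up
  to the length cap (guarded to ≤ 20 items) and must agree with FP-Growth
  exactly — itemsets and integer counts — on randomized inputs; this
  equivalence is part of the test suite.

# Rule analytics

`stage_rules()` keeps rules whose consequent is exactly one stage item.
`repeat_count_table()` ranks transcripts by how many stage rules carry them
in the antecedent, aggregating over levels (a transaction holds at most one
level per feature, so each rule contributes 0 or 1). `top_rules_by_lift()`
orders by lift, then support, then canonical antecedent.
`anchor_feature_rules()` uses a strict lift bound, matching its use as a
plot-level neighbourhood filter. `build_rule_graph()` emits a typed,
bipartite-by-construction phenotype–rule–feature graph (GraphML and edge-list
CSV); figure-level lift cutoffs are exposed as options defaulting to the
global minimum lift. `spearman_matrix()` gives rank correlations among top
transcripts. Box/ring-style summaries are emitted as tidy tables; rendering
is deliberately out of the tested surface.

# The synthetic generator

`generate_cohort()` draws per-feature baseline means, adds Gaussian noise on
the log scale, and exponentiates — a log-normal model chosen to mimic FPKM
skew, not inferred from any real dataset. Informative features get a
location shift of `effect_size * noise_sd` on the log scale in the late
group with alternating sign (both up- and down-regulated markers);
correlated blocks share an equicorrelated per-sample factor; constant
features have exactly zero variance. The `"ptc_tcga_profile"` preset pins
the 375/179 × 60,483 cohort shape for interface tests; values are stored as
base-R doubles (≈ 268 MB at full scale).

What the generator does **not** model — sequencing depth, batch effects,
isoform structure, heavy-tailed outliers, label noise — bounds what passing
tests show: they demonstrate that the machinery recovers planted structure
under a clean generative model, not that any particular real cohort would
yield the same panels or rules.

`generate_planted_transactions()` plants rules directly: an antecedent with
probability support/confidence, then the consequent with probability
confidence, so empirical support and confidence converge to their targets;
remaining items are independent background.

# Problem sizes and reproducibility

Development and acceptance runs use scaled-down study shapes chosen to keep
a laptop-class run comfortable: cohorts of 120–200 samples with 300–1,000
features and ~10 planted markers at d ≈ 2.5, wrapper populations of 8–20
over 3–10 generations, and mining over a few dozen selected transcripts.
The full published shape (554 × 60,483; population 40, 50 generations)
remains the package default and is exercised at the interface level. Every
stochastic step flows from an explicit integer seed; rerunning any pipeline
with the same configuration and seed reproduces artifacts byte for byte.

# Known limitations

* The wrapper's runtime is dominated by classifier fits; slow plug-ins
  (e.g. random forests) are practical for the evaluation roster but not for
  the fitness loop.
* The union merge of per-outer-fold selections can grow with classifier
  variance; the per-fold selection counts are reported so users can apply a
  stricter consensus cut.
* Eq1's standard deviation term is computed within one outer fold (across
  its inner validation AUCs); averaging sd across outer folds is an
  alternative reading of an ambiguous printed formula and is not
  implemented.
* Rule mining on hundreds of transcripts at a 0.3 support floor is fast,
  but lowering min-support substantially on wide panels grows the frequent
  border combinatorially; the miner applies no sampling or approximation.
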