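---
title: "Feature selection and interpretable classification for cardiovascular-risk cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature selection and interpretable classification for cardiovascular-risk cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofs)
```

## The problem

Cardiovascular disease (CVD) risk models built on population survey data
face two linked difficulties: the candidate predictor pool mixes
continuous laboratory values with numerically coded categorical survey
answers, and the outcome is rare relative to the cohort, so the modelling
pipeline must make explicit choices about missingness, class balance, and
— above all — which predictors to keep. `cardiofs` implements a complete,
seeded version of such a pipeline for NHANES-style cohort tables: four
feature-selection strategies of very different character feed a common
classifier benchmark (random forest, RBF-kernel SVM, gradient boosting),
and the winning model is explained with Shapley-value attributions.

Because public-survey microdata cannot ship with a package, a first-class
synthetic cohort generator stands in for the data: it reproduces the
marginal structure of a published 335-case / 335-control descriptive
table exactly where the table is categorical and closely where it is
continuous, and it can plant class-informative features with known effect
sizes so that every selector can be tested against a ground truth.

## Cohort preparation

The preparation chain is deliberately literal:

1. **Missingness filter.** A feature is dropped when *strictly more than*
   30% of its values are missing; a feature missing exactly 30% is kept.
   The threshold is a parameter (`drop_high_missingness(threshold = )`).
2. **Complete cases.** Rows with any remaining missing value are removed.
3. **Random undersampling.** Majority-class rows are discarded uniformly
   at random until the classes are balanced at the minority count
   (335/335 in the motivating study). Every minority row is retained.
4. **Stratified 80/20 split.** Per-class test counts are
   `round_half_up(test_frac * class size)`; a 20% split of 335/335 places
   exactly 67 cases and 67 controls in the test set.

The study that motivated this package narrates balancing before
splitting, so `prepare_cohort()` fixes the order undersample-then-split;
the alternative (split, then balance the training portion only) is a
defensible design but is not what the narrative describes, and mixing the
two silently would change the test-set size.

`descriptive_summary()` produces the usual baseline table: level counts
with chi-squared tests for categorical features, median (IQR) with
Wilcoxon rank-sum tests for continuous ones. The chi-squared test uses no
continuity correction by default (the published table mixes 2x2 and
larger shapes and reports no correction; `correct = TRUE` is available).
The Wilcoxon test uses the normal approximation with tie correction,
switching to exact enumeration only when both groups have at most 25
observations and no ties. P-values below 1e-4 are displayed as
`"<0.0001"`.

## The four selectors

### Pearson + chi-squared redundancy filter

The classical baseline removes *redundant* features, not uninformative
ones. Pearson correlations are computed among continuous features on
pairwise-complete observations; for every pair with `|r| >= 0.90` one
member is removed. Pairwise chi-squared tests among categorical features
remove one member of every pair with `p <= 0.001` (no multiplicity
correction — the rule is a raw threshold by design). Which member of a
flagged pair is dropped is not identifiable from the description we work
from, so the package drops the feature that appears **later in column
order**, scans pairs in lexicographic index order, and skips pairs
involving already-removed features; the full audit trail (partner,
statistic, p-value) is returned and exportable. Re-running the filter on
its own output removes nothing.

### Alternating decision tree (ADT)

The ADT is a boosted rule list: a root prediction score plus rules
(precondition, condition, score pair), where preconditions are
conjunctions along existing tree paths, so several rules can fire at once
and their scores add. Training weights start at 1/t. The package uses the
canonical three-term objective

$$Z(c_1, c_2) = 2\left(\sqrt{W_+(c_1 \wedge c_2)W_-(c_1 \wedge c_2)} +
\sqrt{W_+(c_1 \wedge \neg c_2)W_-(c_1 \wedge \neg c_2)}\right) + W(\neg c_1)$$

minimized over all (path, predicate) pairs each cycle. The source
description names the objective but not its algebraic form; this is the
standard choice consistent with "scores a rule by its ability to separate
the classes", and it is validated in the test suite against brute-force
enumeration on small fixtures. Rule scores are smoothed log-odds
`0.5 log((W+ + eps)/(W- + eps))` with `eps = 1/(2t)` by default — the
smoothing scales with the initial weight granularity and keeps scores
finite on pure partitions. Scores are additionally clamped to ±50: with
`eps = 0` a pure partition has an infinite optimum, and clamping below
the optimum keeps every weight finite while preserving the monotone
decrease of the total boosting weight.

Numerical details that matter for reproducibility:

* Candidate thresholds are midpoints between consecutive sorted distinct
  values within the path's region; categorical predicates test equality
  to each observed level.
* Ties in Z are broken toward the earliest feature in column order, then
  the earliest-created path, then the smallest threshold, with a 1e-12
  comparison tolerance so that floating-point noise in cumulative sums
  cannot flip a tie.
* Fitting stops after `B` cycles (default 50, the configuration reported
  in the study's comparison table) or when no candidate improves on the
  current total weight. The study also mentions evaluating randomly
  sampled values of `B`, without stating the range or selection rule; the
  package exposes `B` as a parameter rather than guessing a sweep.

`features_used()` turns the fitted tree into a feature selection: the
features appearing in any rule, in first-appearance order.

### Cross-validated feature evaluation (CVFE)

CVFE is a stability selector: for each of `e` repetitions the rows are
partitioned (class-stratified) into `c` subsets; each subset contributes
the features with strictly positive gain importance from a tuned
gradient-boosting fit; the repetition keeps the intersection of its `c`
sets; and the final selection keeps features present in at least
`ceiling(p * e)` of the `e` intersected sets ("at least (p x 100)%" read
literally on a discrete count). The positive-gain criterion — rather
than a top-k cut — is chosen because lenient configurations in the
motivating study retain the full 31-feature pool, which only a
nonzero-importance rule naturally produces. The hyperparameter grid for
the per-subset fits (depth {3, 5}, learning rate {0.1, 0.3}, rounds
{50, 100}, 10-fold CV) is a stated default, not a claim about the
original grid, and is fully replaceable; a single-combination grid skips
the inner search, which is how the package's own recovery experiments
run (see *Problem sizes* below).

### Hypergraph feature evaluation (HFE)

Samples are vertices; each discretized feature value is a hyperedge over
the samples sharing it; the class labels partition the vertex set.
Continuous features are discretized first — by equal-frequency quantile
cuts by default (the cohort's laboratory variables are right-skewed, so
equal-width bins would leave near-empty hyperedges; equal-width is
available by flag), with 5 or 10 bins the studied settings. Empty bins
from tied quantiles are dropped.

Each hyperedge is weighted by its stationary mass under the alternating
vertex → incident-hyperedge → member-vertex random walk. On the bipartite
incidence graph this stationary mass is proportional to edge degree,
`|e| / sum(|e'|)`, which closes to `|e|/(N m)` under complete data; the
test suite checks the closed form against an eigen-solved stationary
distribution. The edge importance is

$$I(e) = \pi(e) \cdot \sum_k \left| \frac{n_k(e)}{|e|} - \frac{N_k}{N} \right|,$$

zero exactly when the edge's class mixture is proportional to the global
class sizes and increasing in the total-variation deviation at fixed edge
size — the cut-conductance principle of penalizing proportional mixtures.
The precise functional used by the framework the study cites is not
recoverable from the description we work from; this occupancy-weighted
total-variation deviation satisfies every property that description
states (random-walk weighting, zero at proportionality, growth with
deviation, additive aggregation over a feature's values) and admits an
independent brute-force oracle, which is how it is validated. It is a
documented stand-in, not a bit-level reproduction of the cited method.

Feature scores are sums of their edge importances; the top
`z = round_half_up(beta/100 * m)` features are retained. Half-up rounding
is pinned by the published selection counts (beta 25/50/75 over m = 31
gives 8/16/23). Ranking ties break toward column order.

## Classifier benchmark and confidence intervals

`train_models()` fits random forest, RBF-kernel SVM with probability
calibration, and gradient boosting, each tuned by stratified 10-fold
cross-validated accuracy over a small replaceable grid (the original
grids are unstated; the SVM kernel is likewise unstated and defaults to
RBF, configurable). `evaluate()` reports the four confusion-matrix
metrics to 4 decimals, AUC by the tie-corrected rank-sum statistic
(threshold-free and invariant to monotone transforms of the scores), and
a 95% CI for accuracy. The CI is exact Clopper–Pearson from beta
quantiles: at 111 correct of 134 it reproduces the published
(0.7537, 0.888) where a Wald interval does not, which is what pins the
method choice. Only the accuracy CI is reported, matching how the
published table prints intervals.

## Shapley attributions

`shap_explain()` computes attributions against a background sample:
coalition values are background expectations with the explained row's
values spliced in. With at most 10 features all `2^M` coalitions are
enumerated and the attributions are exact (local accuracy to machine
precision). Above that, the kernel-weighted linear regression
approximation is used, with the sum-to-output constraint eliminated
exactly; when the coalition budget covers all proper coalitions the
regression recovers the exact values, otherwise coalitions are sampled by
the kernel distribution (singletons and complement-singletons always
included, duplicates removed, exact kernel weights). The test suite
checks the additivity, symmetry, and null-feature axioms and agreement
with a permutation-enumeration oracle.

## The synthetic generator: what it does and does not emulate

`generate_cohort()` draws each feature from its own RNG stream derived
from `(seed, feature name)`, so adding a feature never perturbs the
others. Categorical features are realized by exact-count allocation
(largest-remainder rounding of the probability vector, then a seeded
permutation), which makes fixture marginals reproduce published counts
exactly and enables exact descriptive-table tests. Continuous features
are normal or log-normal; log-normal is the default for clinical
variables because published medians/IQRs are right-skewed. Missingness is
MCAR only — the source material states no mechanism, and per-feature
fixture rates are invented where used (the reference fixture itself has
none: the published descriptive table describes the complete-case
sample).

`reference_cohort()` pins log-normal parameters to published medians and
IQRs (`meanlog = log(median)`, `sdlog = log(q75/q25)/(2 * qnorm(0.75))`)
and draws on a permuted mid-point quantile grid, so sample medians track
the targets deterministically. Age and income-to-poverty ratio have no
published medians and use normal distributions calibrated to the
published tail shares (fraction aged 80+, fraction at ratio >= 5); two
count-valued activity variables with published median 0 are modelled as
ordinal categorical (a log-normal cannot have median 0). These choices
are the package's fixture definition, documented here once and not
revisited.

What the generator does **not** emulate: survey weights and the
multistage sampling design, household clustering, informative
missingness, and real between-feature dependence (features are generated
independently within class). Passing recovery tests on this generator
therefore demonstrates correctness of the selectors under planted
independent signal — not their behaviour under the correlated,
confounded structure of real survey data.

## Problem sizes used in the packaged experiments

The recovery and ranking experiments are run at sizes a desk machine
handles comfortably, chosen once as the package's standard experimental
conditions: planted-signal cohorts of 300 cases / 300 controls with 5
informative of 20 features (standardized mean shift 1.0 for continuous,
total-variation distance 0.3 for two-level categorical); 50 seeds for the
HFE and CVFE recovery rates (success = all planted features in the HFE
top 10, or all selected by CVFE at c = 2, e = 5, p = 0.6); and 25 seeds
for the directional comparison of mean test AUC between HFE-selected and
filter-selected feature sets under a fixed RBF-SVM. The CVFE recovery
runs use a single-combination boosting grid (depth 3, learning rate 0.3,
50 rounds), which skips the inner grid search; the consensus logic being
tested is unaffected.

## Known limitations

* The HFE importance functional is a validated stand-in (see above); the
  exact survivor lists of the original study require its real survey
  extract and are not reproducible here.
* The ADT sweep over "randomly selected values of B" is not reproduced;
  `B` is a single exposed parameter.
* Tree-based learners receive categorical features as their numeric
  NHANES codes (ordinal splits); a full one-hot or partition-split
  treatment is out of scope.
* `append_training_data()` refits eagerly on every append with the
  stored configuration; whether the original deployment retrains
  immediately is unknown, and eager refit is the reproducible choice.
* The hosted web interface is out of scope; its batch behaviours
  (prediction, probabilities, attributions, data contribution) are
  provided as functions and a thin CLI script (`inst/cli/cardiofs-cli.R`).
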