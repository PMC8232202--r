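---
title: "Consensus feature screening under class imbalance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus feature screening under class imbalance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In two-class omics screening (e.g. patients vs controls in a metabolomics
intensity matrix) the positive class is often a small minority. Filter
statistics are the standard screening tools because they are cheap and
classifier-free, but different statistics embody different notions of
separation, so their rankings disagree — and the disagreement worsens as the
imbalance ratio grows. `rarank` treats the *panel* of filter rankings as the
object of interest: it re-balances the classes, computes eight rankings, and
fuses them into one consensus list, on the premise that a consensus is more
stable than any single filter on imbalanced data.

Throughout, a dataset has `n = n1 + n2` samples over `p` features; the
positive class C1 is the minority (`n1 <= n2`). The package enforces this
orientation at construction time (`as_feature_table()`), defaulting the
positive label to the rarer one.

## The eight filter statistics

All scorers share a tie rule: when two features receive equal scores, the
one appearing earlier in the table wins. This makes every ranking a
deterministic permutation, which the aggregation stage requires (the
Kendall-τ formula used here assumes tie-free lists).

* **Welch t** — the absolute two-sample t statistic with unequal variances.
  The variant is a deliberate choice (a plain Student t would also do): it
  is the robust default when per-class variances differ, and ordering by
  |t| is equivalent to ordering by p-value for fixed degrees of freedom.
  A feature constant in both classes is flagged and scored 0; a nonzero mean
  gap over zero variance scores `Inf` (and sorts first).
* **Fisher score** — `|x̄1 − x̄2| / sqrt(s1² + s2²)`. The absolute value is
  taken because importance is the magnitude of the shift, not its sign.
* **Hellinger distance** — the squared Hellinger distance between the two
  per-class Gaussians with plug-in sample moments, on the scale `[0, 2]`
  (`2 − 2·sqrt(2σ1σ2/(σ1²+σ2²))·exp(−(μ1−μ2)²/(4(σ1²+σ2²)))`). Zero pooled
  variance is an error naming the offending feature.
* **Relief** — per visited instance, the score of feature j decreases by the
  squared gap to the nearest same-class neighbour (the "hit") and increases
  by the squared gap to the nearest other-class neighbour (the "miss").
  Distances are Euclidean over all features min-max scaled to `[0, 1]` —
  standard Relief practice, since unscaled features would dominate the
  neighbourhoods. By default every instance is visited once in index order,
  making the score deterministic; a seed matters only when `n_iter < n`.
* **ReliefF** — as Relief, averaging over the k nearest hits and misses
  (default `k = 10`, Kononenko's convention, clipped to the smaller class
  size minus one). `k = 1` reduces exactly to Relief, which the tests
  exploit.
* **Information gain** — continuous features are discretised by the best
  *binary* midpoint split (the decision-tree convention): the score is the
  maximal entropy reduction over all thresholds between consecutive distinct
  sorted values, with base-2 logarithms. Constant features gain 0.
* **Gini index** — the same threshold search, minimising the child-weighted
  Gini impurity; smaller is better. A constant feature keeps the parent
  impurity.
* **R-value** — the fraction of instances whose k nearest neighbours *on the
  single feature* (self excluded) contain more than θ opposite-class
  members; defaults `k = 5`, `θ = k/2`, strict inequality. Distance ties
  are broken by ascending sample index, so the statistic is well defined on
  discrete data (including identical point multisets in both classes).
  Smaller means less class overlap, hence more important.

Each scorer is checked against an independent brute-force re-implementation
(explicit loops, exhaustive threshold/neighbour scans) on batches of random
tables, plus the closed-form identities: 1 bit of entropy and Gini 0.5 at
balance, Hellinger 0 for identical class distributions, information gain
equal to the full entropy for a perfectly splitting feature, R-value 0 for
well-separated classes.

## Rank aggregation

The consensus δ\* minimises `Σ wi · d(δ, fi)` with uniform weights (the
package treats the eight filters as equally trustworthy; weights are
exposed for callers who disagree). The distance is the *unweighted* Spearman
footrule `d(a, b) = Σt |ra(t) − rb(t)|`: a score-weighted footrule exists in
the rank-aggregation literature, but it presumes the lists share a score
scale, which eight heterogeneous filter statistics do not. The weighted form
is available behind the `rank_scores` argument of `footrule_distance()` for
callers who have such a scale.

Two optimisers are provided:

* `aggregate_brute_force()` enumerates all p! permutations (capped at
  p = 8), breaking ties lexicographically — the exact reference.
* `aggregate_ce()` is a cross-entropy Monte Carlo search: a p×p
  feature-by-position probability matrix starts uniform at 1/p; each
  iteration samples N permutations position by position (renormalising over
  the features still unplaced), scores them, and refits the matrix to the
  elite fraction ρ with exponential smoothing
  `P ← w·F̂ + (1−w)·P`. The best-ever permutation is returned when the best
  objective has been flat for `window` iterations.

The cross-entropy hyperparameters are not dictated by the aggregation
objective itself; the defaults follow common cross-entropy practice and are
all exposed via `ce_control()`: `N = 10·p²` samples per iteration (enough to
make elite counts of ~p² informative about a p×p matrix), elite fraction
ρ = 0.1, smoothing 0.7, cap of 100 iterations, stall window 5. On small
problems the search is expected to hit the exact brute-force optimum
essentially always; the test suite requires at least 19 of 20 random
problems at p = 5 with 3–8 lists. The permutation sampler and the batch
footrule evaluation are the computational hot spots and are implemented in
C++ (drawing from R's RNG, so runs are seed-reproducible).

Concordance between two rankings is Kendall's τ — concordant minus
discordant feature pairs over `p(p−1)/2` — and a panel of m lists is
summarised by the mean τ over all `m(m−1)/2` pairs.

## Re-balancing regimes

Seven cases cover the standard re-sampling space; classes are exactly
balanced after every case except the pass-through:

| case | type | mechanism | result |
|------|------|-----------|--------|
| 1 | none | — | unchanged |
| 2 | hybrid | SMOTE + random removal | `(2n1, 2n1)` |
| 3 | hybrid | fully synthetic smoothed bootstrap | `(⌊n/2⌋, ⌈n/2⌉)` |
| 4 | over | random duplication | `(n2, n2)` |
| 5 | over | smoothed-bootstrap minority | `(n2, n2)` |
| 6 | under | random removal | `(n1, n1)` |
| 7 | under | majority replaced by `n1` smoothed-bootstrap draws | `(n1, n1)` |

Design choices that the case definitions leave open:

* **Case 2 target level.** "Majority cut to the size of the enlarged
  minority" does not fix the level; the package doubles the minority with
  100% SMOTE and cuts the majority to `2·n1` — the most common SMOTE+RUS
  recipe consistent with that sentence. It requires `n2 ≥ 2·n1` and errors
  otherwise.
* **Case 7 reading.** Generating synthetic *majority* examples only
  under-samples if the synthetic draws *replace* the majority at the
  minority's size; that is the reading implemented.
* **Case 3 split.** "Approximately equal" is made concrete as
  `⌊n/2⌋` minority / `⌈n/2⌉` majority, keeping the positive class the weak
  minority for odd n.

SMOTE draws one scalar `u ~ Uniform(0,1)` per synthetic point (not per
coordinate), so every synthetic point lies on the segment between its seed
and one of the seed's k = 5 nearest minority neighbours — a property the
tests verify geometrically. The smoothed bootstrap perturbs a uniformly
chosen class member with a diagonal Gaussian kernel whose per-feature
bandwidths follow Silverman's rule `0.9·min(sd, IQR/1.34)·nk^(−1/5)`;
degenerate features (or singleton classes) fall back to 1% of the overall
feature scale, with a message. A `bandwidth_scale` multiplier exposes the
plain-bootstrap limit (`scale = 0`) used in the tests.

All cases are bit-for-bit reproducible from `(input, seed)`, and every
output row carries a provenance flag (`original` rows are bit-identical to
their source).

## Evaluation

* **Gmean / F1** come from 0.5-thresholded out-of-fold class probabilities
  (majority vote of the forest). The threshold is a convention, exposed as
  an argument; zero-denominator ratios are reported as 0 with a warning.
* **AUCROC** uses the Mann-Whitney formulation (ties ½), which is exactly
  the rank-sum estimator and invariant under monotone score transforms.
* **AUCPRC** uses average precision with tied scores processed as one
  block — constant scores then give the prevalence exactly. Trapezoidal PR
  integration is available but not the default, because linear
  interpolation in PR space is optimistic.
* **Top-k selection** runs stratified 5-fold cross-validation of a
  500-tree random forest (`ranger`) for every k = 1..p over the top-k
  features of the supplied ranking; `k_opt` is the smallest k attaining the
  maximal mean out-of-fold AUCPRC (parsimony tie-break). If the minority is
  smaller than the fold count the function aborts with a message rather
  than silently producing folds without positives.
* **Resampling placement.** `run_rar()` defaults to re-applying the
  re-balancing case *inside each training fold* (`cv_resample =
  "within_fold"`), which keeps synthetic or duplicated rows out of the
  held-out folds — the leakage-safe protocol. `"pre_split"`
  cross-validates the re-balanced table directly, reproducing the
  whole-dataset workflow in which re-balancing precedes evaluation; the
  package keeps both because the optimistic variant is what published
  screening tables typically report.

`summarize_tables()` operates on the bundled plain-text transcriptions of
the published method-comparison tables and counts, per row, whether the
focal method reaches the row maximum, *ties included* — a tie means the
method matched the best competitor. The three reported comparisons are
described in `?summarize_tables`.

## The simulator and what it does (not) emulate

`generate_two_class_gaussian()` draws the majority class from `N(0, Σ)` and
the minority from `N(μ, Σ)`; the study designs fix Σ to the identity,
`n = 960`, and mean shifts `(2.4, 2.2, …, 1.0)` — all features informative
in the 8-feature design, eight zero-shift features appended in the
16-feature design. μ0 is pinned at zero because only the difference of
means matters to every statistic involved. The imbalance ratio r splits n
exactly (`n·r/(r+1)` vs `n/(r+1)`; all five stock ratios 1, 3, 9, 31, 95
divide 960 evenly), and each (ratio, repeat) cell of a concordance study
receives an independent child seed derived from the base seed, so studies
are reproducible and cells are independent.

`concordance_study()` reports the repeat-averaged mean pairwise τ per
ratio. The acceptance script runs both designs at the balanced ratio with
100 repeats; the test suite uses 25 repeats for the concordance means and
50 for the feature-recovery property, sizes chosen to keep the default
suite comfortably interactive while leaving Monte-Carlo error well inside
the asserted tolerances.

The simulator emulates the *geometry* that drives filter disagreement
(graded effect sizes, irrelevant features, exact class-count control). It
does **not** emulate feature correlation (Σ is identity by default, though
any SPD Σ is accepted), heavy tails, skewness, batch effects, missingness
or intensity-dependent noise — all present in real metabolomics matrices.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative imbalance effects, not performance claims on real data.

## Numerical conventions and degenerate inputs

* Ties: feature-order tie-breaks in every ranking; ascending-index
  tie-breaks in every neighbour search; lexicographic tie-break among
  equally optimal permutations; smallest-k tie-break for `k_opt`.
* `±Inf` scores are legal and sort to the extremes; `NaN` scores cannot
  arise because the degenerate cases (zero variances, constant features,
  empty splits) are intercepted and defined explicitly.
* All stochastic stages (resampling, cross-entropy search, fold
  assignment, forests, simulator) consume explicit seeds; `run_rar()` fans
  one seed into per-stage child seeds so stages can be re-run in isolation.

## Known limitations

* Binary classes only; the multi-class generalisations of the filters are
  out of scope.
* The cross-entropy search is a heuristic: beyond exhaustive reach (p > 8)
  optimality cannot be certified, only the non-increasing trace and the
  small-p equivalence evidence.
* Case 2 is undefined for mild imbalance (`n2 < 2·n1`) by construction.
* The bundled comparison tables are transcriptions of printed values and
  inherit their two-decimal rounding; the tie-inclusive counting rule makes
  the summaries sensitive to that rounding.
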