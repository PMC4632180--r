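---
title: "CPEMM: model, search mechanics and design choices"
author: "cpemm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CPEMM: model, search mechanics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpemm)
```

## The problem and the method

Clinical tabular datasets for multiclass diagnosis — for example
discriminating cognitively normal individuals (NL) from mild cognitive
impairment (MCI) and Alzheimer's dementia (AD) using neuropsychological
scores and imaging-derived volumes — typically carry a few dozen to a few
hundred attributes, of which only a small subset is jointly informative.
`cpemm` implements an ensemble *wrapper* feature-selection pipeline for
this setting, in three phases:

1. **Base-classifier choice.** Candidate base learners (a C4.5-style
   decision tree, naive Bayes, random forest, RBF-kernel SVM) are compared
   by stratified cross-validation, including an ablation condition in
   which dominant attributes (such as a clinical dementia rating) are
   removed to probe robustness (`compare_base_classifiers()`).
2. **Subset search.** Binary Particle Swarm Optimisation explores the
   $2^d$ space of feature subsets. Every visited subset receives a
   *merit*: the stratified 5-fold cross-validated accuracy of a bagged
   ensemble of the base learner restricted to that subset
   (`run_pso()`, `subset_merit()`). All distinct visited subsets are
   deduplicated and ranked by non-increasing merit.
3. **Merit Merge.** The ranked list is walked top-down and consolidated by
   three cases (`merit_merge()`): equal-merit subsets are evaluated
   individually and as a merged union, and the union is kept only when it
   *strictly* improves accuracy (Case 1); if more than half of the list
   ties at the top merit, the search is re-run at a higher iteration count
   to obtain a sharper, smaller-subset ranking (Case 2); the walk stops at
   the first successive subset whose merit drops by more than a threshold
   $\delta$ (Case 3). The final feature set is the accuracy-best outcome
   of the walk; the deployed model is a bagged ensemble refit on it.

`cpemm()` runs phases 2–3 in one call and returns a classed fit with
`print`, `summary`, `predict` and `plot` methods.

## The wrapper merit

For a subset $S$, `subset_merit()` partitions the data into $k$
stratified folds (default $k = 5$; per-class fold sizes differ by at most
one), fits a bagged ensemble of $B = 10$ base learners on each training
fold restricted to $S$, predicts the held-out fold by majority vote (ties
broken by the larger training class frequency, then class-declaration
order), and returns the mean fold accuracy. The merit is a number in
$[0, 1]$ and is fully deterministic given the seed: fold assignment,
bootstrap resampling and every tie-break are seeded, and all candidate
subsets within one search share the same folds and bootstrap row sets, so
subset comparisons are paired rather than independently resampled.

A merit evaluation costs $k \times B = 50$ ensemble-member fits. Because a
single search visits one to two thousand distinct subsets, the default
C4.5-style base tree and the whole merit loop are implemented in compiled
code; a search over a 20-feature space on 750 instances completes in about
a minute on one core.

## Binary PSO mechanics

Particles carry a binary inclusion mask $x$ and a real velocity $v$ per
feature. Each iteration updates, per particle and bit,

$$v \leftarrow w v + c_1 r_1 (p - x) + c_2 r_2 (g - x), \qquad
  x \leftarrow \mathbb{1}\{u < \sigma(v)\},$$

where $p$ is the particle's personal best, $g$ the swarm's global best,
$r_1, r_2, u \sim U(0,1)$, $\sigma(v) = 1/(1+e^{-v})$ is the sigmoid
transfer, and velocities are clamped to $\pm v_{\max}$. Defaults follow
the canonical constriction-style binary-PSO settings: $w = 0.729$,
$c_1 = c_2 = 1.49445$, $v_{\max} = 4$, swarm size 30, 60 iterations
(the useful range being 60–100: longer searches tend to *shrink* the best
subset rather than grow it). An all-zero mask is repaired by setting one
uniformly random bit, since an empty subset cannot be evaluated.

Personal and global bests update on strict merit improvement, and also
when an exactly equal merit is achieved by a strictly smaller subset; the
final ranking sorts ties the same way (fewer features first, then
lexicographic mask order). This parsimony tie-break matters because a
feature that the trees never split on leaves the merit exactly unchanged,
so minimal subsets dominate their padded variants whenever the padding is
truly inert.

## The Merit Merge walk

"Equal merit" is equality within $10^{-6}$: cross-validated accuracies
are exact rationals (multiples of one over the fold size), so genuine ties
are exact and the tolerance only absorbs floating-point noise. "Much lower
merit" defaults to an absolute drop of $\delta = 0.05$; setting
$\delta = 1$ disables Case 3 and evaluates the whole ranking. Case 2
escalates through the iteration schedule 60 → 80 → 100 and then gives up
gracefully, returning the best result so far with a flag
(`schedule_exhausted`), since an unresolved flood of equal merits is a
recognised limitation of the procedure.

Accuracy inside the walk is estimated under the same protocol as the
final report (default: stratified 5-fold CV) but with a seed distinct
from the merit seed, so Phase III never re-reads the resampling splits the
search optimised against. The judge is the *bagged* ensemble of the
configured base classifier rather than a single tree: the deployed model
is the bagged ensemble, and a single C4.5 tree's cross-validated accuracy
fluctuates by roughly ±0.01 on 750 instances, which is too noisy to
arbitrate between candidates whose true difference is a few thousandths.
The C4.5 tree is the default judge; naive Bayes and random forest are
supported, and an RBF-SVM judge is accepted but warns, reflecting its
comparatively poor multiclass recall in this domain. Because the selected
subset is the accuracy argmax over all walk evaluations, and the
top-ranked subset is always evaluated, the reported accuracy can never
fall below the top-ranked subset's accuracy.

## Base learners

* **C4.5-style tree (`"c45"`)** — implemented in the package (Rcpp):
  binary splits chosen by information gain; Quinlan's MDL correction for
  continuous attributes (the gain of a numeric split is reduced by
  $\log_2(\#\text{thresholds})/m$, the description cost of naming the
  chosen cut) and the analogous $\log_2(2^{k-1}-1)/m$ cost for a
  $k$-category bipartition; pessimistic-error post-pruning at confidence
  0.25 via the binomial upper confidence limit; minimum leaf size 2.
  Missing values need no imputation: rows missing the test value follow
  the majority branch and split gains are damped by the non-missing
  fraction. Without the MDL correction the tree overfits
  class-independent attributes badly (bagged CV accuracy on pure-noise
  3-class data falls ~6 points below the majority rate); with it the tree
  tracks the majority rate on noise. The test suite cross-checks the tree
  against `rpart` on separable and noisy fixtures.
* **Naive Bayes (`"nb"`)** — `e1071::naiveBayes`, Gaussian per class for
  numeric features, frequency with Laplace $\alpha = 1$ for nominal ones.
* **Random forest (`"rf"`)** — `randomForest`, default 600 trees, the
  point where out-of-bag error has levelled off on data of this shape.
* **RBF SVM (`"svm_rbf"`)** — `e1071::svm` (libsvm) with the kernel
  $k(x_i, x_j) = \exp(-\gamma \lVert x_i - x_j \rVert^2)$; nominal
  features are one-hot encoded for the kernel space; `grid_search_svm()`
  tunes $(C, \gamma)$ over the standard log2-spaced grid by stratified CV
  with ties to the smaller $C$, then smaller $\gamma$.

For every learner, `predict()` is defined as the row-wise argmax of
`predict_scores()` with ties to the first class in declaration order, so
labels and scores can never disagree (libsvm's independent
probability/label paths are reconciled the same way).

## Preprocessing

`preprocess()` applies, in fixed order: removal of features with *more
than* 40% missing cells (strict inequality, idempotent), class-wise
imputation (numeric missing cells get the within-class mean, nominal ones
the within-class mode with ties broken by category declaration order;
classes with no observed value fall back to the global statistic),
z-score normalisation of all numeric columns with the sample (n−1)
standard deviation, and optional min-max rescaling of named columns. The
source material does not enumerate which attributes were rescaled to
[0, 1], so rescaling is opt-in by column name while z-scoring is the
default for every numeric column. Zero-variance columns normalise to all
zeros. Recognised missing tokens are the empty string, `?` and `NA`.

## Evaluation statistics

Reports carry the k×k confusion matrix (rows true, columns predicted),
overall accuracy, and per-class precision $TP/(TP+FP)$, recall
$TP/(TP+FN)$ (both defined as 0 when the denominator vanishes) and
one-vs-rest accuracy $(TP+TN)/n$ — the last because per-class accuracy
tables in this literature do not define the quantity, and one-vs-rest
collapsing is the conventional reading. One-vs-rest AUC is computed as
the Mann–Whitney probability (rank statistic, ties counted ½), which
equals the trapezoidal ROC area but handles ties without special cases,
and is invariant under monotone score transforms; the multiclass summary
is the unweighted macro average. Press' Q,

$$Q = \frac{(m - np)^2}{m(p-1)},$$

for $m$ samples, $n$ correct and $p$ groups, is referred to $\chi^2$ with
one degree of freedom — the conventional reference for this statistic.

## The synthetic generator

`generate_synthetic()` emulates the *statistical shape* of a
neuropsychological study extract: by default 750 instances in three
imbalanced classes (NL 200 / MCI 400 / AD 150) with 48 features — 6
informative, 6 redundant, 36 noise. Informative feature $j$ is
$N(\mu_{cj}, 1)$ with class means spaced $\Delta = 1.5$ SD apart along a
class ordering drawn independently per feature, so no single feature
ranks the classes the same way and joint use of several features is
required. Redundant features are an informative source plus
$N(0, \sigma_r = 0.1)$ — deliberately near-duplicates, so that minimal
subsets are testable (the optimal subset excludes them, but only barely:
a redundant copy retains about 99.5% of its source's separation).
Noise features are $N(0, 1)$ independent of the class. Missingness is
MCAR at a configurable rate; an optional fraction of features is
quantile-binned into three-category nominals. The two-class companion
(`generate_two_class()`) defaults to 650 × 108 with classes 400/250 and
8/8/92 features — the class split and feature roles are this package's
choice; only the overall shape is meant to be representative.

What the generator does **not** emulate: real score distributions
(bounded, skewed, discrete scales), correlated noise blocks,
informative-missingness, longitudinal visit structure. Passing tests on
this generator therefore demonstrate the mechanics of search, merging and
evaluation — not clinical performance.

## Determinism

One master seed determines everything: child seeds are derived by a fixed
integer hash (`seed`, salt) → [1, 2³¹), the compiled merit loop uses its
own splitmix64 stream seeded the same way, and every tie-break is
deterministic. Two runs with the same seed produce byte-identical output
files; no output contains timestamps.

## Known limitations

* **Selection optimism at small effect sizes.** The merit is a single
  5-fold CV estimate; its between-subset jitter on 750 instances
  (≈ ±0.004) exceeds the true merit penalty of one spurious feature
  (≈ 0.001). Maximising over ~1800 visited subsets therefore favours
  lucky masks, and the recovery of exactly the planted feature set
  degrades when redundant near-duplicates exist — the acceptance suite's
  planted-recovery check documents this at its stated conditions. A
  repeated-CV merit would trade runtime for stability; the single-CV
  definition is kept as specified.
* Case 1 merges whole equal-merit groups at once (not pairs); with large
  groups the union can be coarse.
* The C4.5 approximation uses information gain with the MDL correction
  rather than gain ratio, and pessimistic pruning rather than
  subtree-raising; categorical splits enumerate bipartitions exhaustively
  only up to 20 categories.
* Problem sizes in the examples and tests (hundreds of instances, tens of
  features, swarm 30 × 60 iterations) match the clinical-cohort scale the
  package targets;
  much wider data (thousands of features) would want a filter-style
  pre-reduction before the wrapper search.
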