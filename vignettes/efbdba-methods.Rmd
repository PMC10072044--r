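---
title: "Methods: two-stage biomarker selection with efbdba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage biomarker selection with efbdba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efbdba)
```

# The problem

Gene-expression microarrays measure thousands of features on a few dozen
samples. Only a handful of genes discriminate the two phenotype classes
(tumor vs. normal, subtype A vs. B); the rest are noise or redundant copies
of the signal. `efbdba` selects a small, highly discriminative feature
subset in two stages: a cheap **ensemble filter** that shrinks the feature
space to a candidate pool, and an expensive **wrapper** that searches
subsets of the pool with a hybrid binary metaheuristic scored by
cross-validated SVM accuracy.

# Preprocessing

The fixed order is: duplicate-feature averaging, Tukey-fence outlier
flagging, KNN imputation, z-scoring.

* **Duplicates** (identical feature ids, e.g. repeated probes) are averaged
  per sample, skipping missing cells.
* **Tukey fences**: per feature, values outside
  $[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$ are flagged missing.
  The fence multiplier defaults to the classic $k = 1.5$ and quartiles use
  linear interpolation (type-7); both are configuration choices, since the
  test itself is named but not parameterized in the source method.
* **KNN imputation** ($k = 5$) fills each missing cell with the mean of the
  feature over the $k$ nearest samples, with distances computed over
  mutually observed features only. The fill is single-pass (no iterative
  re-imputation), so it is deterministic and order-independent.
* **z-score** uses the *population* SD (divisor $n$): the transform is a
  scaling, not an inference. Constant features become all-zeros.

Running the pipeline twice changes nothing, provided the cleaned data stay
inside the fences; on heavy-tailed data a second pass can legitimately flag
new tail points, which is why the idempotence property is only asserted on
bounded data.

# Stage one: the ensemble filter

The pool is the intersection of two feature sets: an improved
fast-correlation-based filter (FCBF) selection and the top-$k$ features by
Fisher score ($k = 100$ by default). An empty intersection falls back to
the union, because the wrapper needs a non-empty pool.

## Class relevance

Each feature's per-class value vectors are SMOTE-balanced to equal length,
sorted ascending, and compared; the relevance is
$r_{cf} = 0.8\,(1 - r_{pn})$, capped at 0.8 so that borderline features are
never irrevocably deleted.

The similarity $r_{pn}$ is the **uncentered cosine** of the sorted class
profiles, clamped to $[0, 1]$. This is a deliberate design choice: a
centered Pearson correlation is exactly invariant to adding a constant to
either vector, so it cannot distinguish a feature whose classes differ only
in mean — precisely the signal a univariate relevance score must detect.
The uncentered form is location-sensitive, equals 1 for identical class
profiles (relevance 0), and stays in $[0,1]$ for sorted profiles of
uninformative features, matching the intended range of the
$0.8\,(1-r_{pn})$ map. Sorting before comparison is the only pairing of the
two class vectors that is invariant to sample order within class.

SMOTE balancing uses $k = 5$ neighbors and synthesizes
$s_k = s_i + \mathrm{rand}(0,1)\,\lvert s_i - s_j\rvert$ with an
*elementwise absolute* difference. This differs from conventional signed
SMOTE interpolation; the form is kept verbatim from the source method.

## Redundancy and complementarity

Candidates above the relevance threshold are processed in decreasing
relevance. The leader joins the optimal set $O$; every remaining candidate
whose absolute Pearson correlation with the leader is at least its own
relevance is eliminated (the approximate Markov blanket rule). Among each
round's casualties, the feature with the greatest **complementarity** to
the leader is rescued into a complementary set: complementarity is the mean
Manhattan distance, over the two feature dimensions, between randomly drawn
samples and their heterogeneous (opposite-class) nearest neighbors — a pair
of features that jointly separates the classes scores high even when each
margin is silent. The heterogeneous neighbor is by default the
opposite-class sample closest in sample-order index (the literal reading of
the source); a Euclidean rule is available via `comp_neighbor`. Rescued
features are passive: they never act as leaders.

The relevance threshold is a quantile by default (keep the top 20% of
features by $r_{cf}$) because the source sets no absolute value and admits
prior knowledge was used; an absolute `delta` can be configured instead.

## Fisher score

$J = S_B / S_\omega$, between-class over within-class variance, with an
$\varepsilon = 10^{-12}$ floor on the denominator so perfectly separated
features get a large finite score. $J$ is invariant to shifting and scaling
a feature, which the tests assert.

# Stage two: the hybrid wrapper

Subsets of the pool are binary masks. The fitness of a mask is

$$ f = \begin{cases} \mathrm{acc} - \beta\,\mathrm{num}/L, & \beta < 0.9\\
\mathrm{acc}, & \text{otherwise}\end{cases}
\qquad \beta = \frac{\lfloor g/100\rfloor \cdot 100}{G} + 0.1 $$

where `acc` is stratified 5-fold CV accuracy of a linear SVM on the masked
features, `num` the subset size and $L$ the pool size. The penalty weight
$\beta$ steps up every 100 generations; once $\beta \ge 0.9$ the search
optimizes accuracy alone. The empty mask gets sentinel fitness $-1$ and is
repaired (one random bit) before evaluation.

## Improved binary DE

* **Mutation** is sparsity-inducing: per dimension, $\mathrm{diff} = 0$ if
  the first two donors agree, else $F x_{r1,j}$;
  $pr = \tanh(\mathrm{diff})$; the mutant bit is 1 only if
  $pr \ge \mathrm{rand}$ *and* the third donor's bit is 1. The mutant
  support is therefore a subset of the third donor's support.
* **Scaling factor** $F = f_{min} + \frac{G-g+1}{G}(f_{max}-f_{min})$,
  decreasing from 0.9 to just above 0.1. The printed source formula divides
  by $g$, which explodes at early generations and contradicts its own
  requirement $F \in [0,1]$; the divisor is corrected to $G$ and the value
  clamped.
* **Crossover** is binomial with a guaranteed coordinate (`jrand`) and the
  adaptive rate $CR = \alpha\,\frac{2e^{-g/G}}{e^{g/G}+e^{-g/G}}$, which
  decays from $\alpha$ to $0.2384\alpha$ (0.23 for $\alpha=1$, 0.023 for
  $\alpha=0.1$).
* **Selection** is greedy one-to-one; ties keep the incumbent.

## Binary African vultures step

During the first 40% of generations each individual draws a starvation rate
`SR` (original-AVOA form, $w = 2.5$); when $|SR| < 1$ the individual takes
a vulture move instead of a DE step. The leader is chosen by
opposition-based learning: the population best `x_first` is flipped in
exactly $\lfloor L/2\rfloor$ random bits to form `x_new`, and `x_first`
leads with probability equal to its clamped fitness. With $|SR| \ge 0.5$
the move explores (toward the leader with probability $P_1$, else a random
difference move); with $|SR| < 0.5$ it takes a transition move (siege-fight
with probability $P_2$, else rotating flight). Continuous positions are
binarized through a left-shifted sigmoid with an *inverted* threshold
(`rand > s`), kept verbatim; the inversion biases toward sparsity and is
counteracted by subjecting every vulture child to the same parent-vs-child
selection as DE children — unconditional replacement would let it destroy
good masks. The starvation-rate and movement formulas are not printed in
the source method (it defers to the cited AVOA paper), so each is isolated
behind one function for easy substitution.

## Global best

The $\beta$-weighted fitness is time-varying, so raw fitness cannot be
compared across generations. The reported subset comes from an elitist
archive ordered lexicographically: higher CV accuracy, then fewer features,
then first found. Its accuracy trace is non-decreasing by construction.

## The fitness classifier

The source method names only "SVM"; the kernel and cost are unknowable from
it. The package uses a **linear SVM with C = 1**, the standard choice for
$n \ll p$ expression data; this is the reproduction's single largest
unknown and is exposed via `svm_cost`. No SVM library is required: the
classifier is an L1-loss dual coordinate-descent solver (deterministic
cyclic sweeps) implemented in C++, verified in the tests against an
independent projected-subgradient hinge-loss minimizer. CV folds are
stratified and drawn once per run, so fitness is a pure function of the
mask (enabling caching and the monotone archive).

# The synthetic world

`make_synthetic()` emulates the microarray regime: default 100 samples by
1000 features, 20 informative features with class means $\pm e/2$
($e = 2$, i.e. a two-SD separation — a typical well-powered microarray
effect), 10 redundant near-copies (jitter SD $0.1\sigma$), 5 complementary
pairs whose margins are class-symmetric sign mixtures but whose product
separates the classes, the rest independent Gaussian noise, optional
missing cells, Tukey-detectable outliers and class imbalance. It returns
the ground-truth indices, which the tests use to assert recovery (the
filter retains at least 16 of 20 planted features; the wrapper reaches
$\ge 0.9$ CV accuracy with $\le 10$ features on a 100-feature pool).

What a green test does *not* establish: real microarray noise is not
Gaussian, probe effects and batch structure are absent, and the generator's
redundant features are exact near-copies rather than co-regulated genes.
Recovery on this world shows the machinery works as designed, not that it
reproduces any published per-dataset accuracy (those depend on external GEO
data and are out of scope).

# Numerical choices and degenerate inputs

* Pearson correlation of a constant vector is defined as 0; the class
  relevance of an all-zero profile pair is 0 (indistinguishable classes).
* Welch $t$ uses sample variances and Satterthwaite degrees of freedom;
  identical constant groups give $t = 0, p = 1$.
* Fold change is undefined (reported `NA`) when the negative-class mean
  is 0.
* Metrics with zero denominators (no predicted positives) return 0.
* Ties are always broken toward the lower index (quartile interpolation,
  neighbor ordering, relevance sorting), making every stage deterministic
  given the seed. All randomness flows from `bdba_config(seed = )`.

# Known limitations

* Only two-class problems are supported.
* The relevance score, SMOTE variant and binarization are kept faithful to
  the source method where it is explicit; where it is silent (pairing,
  thresholds, kernel) the defaults documented above are choices, and other
  choices could change which features are selected.
* The wrapper's cost is one SVM CV per *new* mask per generation; for pools
  much larger than ~200 features, reduce `G`/`NP` or tighten the filter.
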