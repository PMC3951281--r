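---
title: "Multi-instance learning systems for gene function prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-instance learning systems for gene function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mihclust)
```

## The problem

Gene function prediction from time-course expression data is a multi-label
learning problem with an awkward label space.  Genes are annotated to Gene
Ontology (GO) terms, but most individual terms carry only a handful of
annotated genes -- far too few positive examples to train a classifier.
The standard remedy is to *up-propagate* annotations along the GO `is_a`
hierarchy until classes become learnable, either until every class reaches a
minimum gene count (gene-number clustering, GNC) or up to a fixed depth of
the DAG (GO-level clustering, GOLC).  Both strategies buy statistical power
at the price of biological resolution: the ontology's upper structure
groups terms by curated semantics, not by expression behaviour, so
up-propagated classes mix genes with unrelated expression dynamics.

`mihclust` implements a third construction, multi-instance hierarchical
clustering (MIHC).  Each GO term is treated as a *multi-instance bag* whose
instances are the expression profiles of its annotated genes, and terms are
clustered agglomeratively under a bag-level distance.  Classes are then
groups of terms whose genes actually co-vary in the experiment at hand,
which is the signal the downstream classifiers use.

## Pipeline overview

1. **Preprocessing** (`read_expression()`, `preprocess()`): profiles are
   gap-filled, shifted so each gene starts at zero log-ratio, and smoothed
   by a short centred moving average.
2. **Gene selection** (`build_non_noise_system()`): per term, keep a greedy
   maximal clique of mutually significantly correlated genes -- the
   "non-noise system" `(E*, A*)`.
3. **Learning-system construction** (`gnc()`, `golc()`, `mihc()`): build
   classes and the binary gene x class label matrix.
4. **Classification** (`train_mlsvm()`, `train_mlknn()`): binary-relevance
   SVMs with class-imbalance loss amplification, and a similarity-sum
   multi-label KNN.
5. **Evaluation** (`run_protocol()`): balanced leave-a-percent-out splits,
   per-class ROC/AUC, summaries over a grid of training shares.

```{r pipeline, eval = FALSE}
syn  <- generate_synthetic(seed = 1)
expr <- preprocess(syn$expr)
nns  <- build_non_noise_system(expr, syn$annot, alpha = 0.05)
sys  <- mihc(nns)$system
run_protocol(sys, expr, clf = "mlsvm", n_grid = 0.5, reps = 20, seed = 1)
```

## Models and choices

### Preprocessing

Raw log-ratio series are aligned by subtracting each gene's first value
(`values[, 1] == 0` after the shift), mirroring the usual treatment of
cell-cycle time courses where only the shape of the response matters.
Spikes are damped with a centred moving average of width `smooth_window`
(default 3, the smallest window that does any smoothing); at the series
edges the window truncates to the available neighbours so the series keeps
its length.  Note the order of operations: the baseline shift happens
*before* smoothing, so with `smooth_window > 1` the first smoothed value is
generally no longer exactly zero.  Missing cells are linearly interpolated
along the time axis (nearest observed value at the edges); genes missing
more than 30% of their points are dropped with a warning, a conventional
missingness ceiling for microarray series.  Pearson correlation is
invariant to the baseline shift, so the shift matters only for
visualisation and for classifiers operating on raw coordinates.

### Gene selection

For each term the package builds a graph over its annotated genes, joining
two genes when the two-sided t-test on their Pearson correlation,
`t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom, is significant
at `alpha` (default 0.05, no cross-pair correction by default; a per-term
Bonferroni flag is available).  Finding the maximum clique of this graph is
NP-hard, so a deterministic greedy heuristic is used: seed with the
highest-degree vertex, repeatedly add the candidate adjacent to all current
members with the highest degree among the remaining candidates, breaking
ties lexicographically by gene id.  The result is always a maximal (not
necessarily maximum) clique; the test suite checks it against exhaustive
search on small random graphs.  Terms whose clique falls below `min_clique`
(default 2 -- a single gene carries no co-expression evidence) are dropped.

### Bag distance and MIHC

The instance distance between two profiles is `d(x, y) = 1 - r(x, y)`,
mapping perfect correlation to 0 and perfect anti-correlation to 2; a
constant profile has no defined correlation and is assigned the maximum
distance.  Bags are compared with Hausdorff-family aggregates of
nearest-instance distances.  The default is the average variant,

    D(A, B) = (sum_{x in A} min_{y in B} d(x, y)
             + sum_{y in B} min_{x in A} d(x, y)) / (|A| + |B|),

which is symmetric, zero on identical bags, and markedly more robust to
single outlying instances than the classic maximal variant; both the
`max_hausdorff` and `min_hausdorff` variants are also provided.  Clusters
are merged bottom-up, always joining the pair at minimum bag distance (ties
resolved by the lowest pair of cluster indices), and a merged cluster is
the *union of the instance sets* -- clusters stay genuine multi-instance
samples rather than linkage summaries, so the union of class gene sets
always equals the non-noise gene set.

**Terminal factor.**  Agglomeration stops when the minimum pairwise
distance exceeds `stop_tau`.  When `stop_tau` is not supplied, the package
computes the complete merge sequence and cuts it at the midpoint of the
largest gap between consecutive merge heights.  This knee rule was chosen
after the obvious data-adaptive alternative -- the mean of the initial
distance matrix -- proved unreliable: because the average-Hausdorff
distance between unions *decreases* as bags accumulate instances (the
minimum runs over more candidates), inter-group cluster distances routinely
fall below the initial-matrix mean, which sits between the within- and
between-group distance scales, and well-separated groups get merged anyway.
The largest-gap cut keys on the same separation the dendrogram itself
exhibits, remains parameter-free, and reduces to sensible behaviour in the
degenerate cases (`stop_tau = 0` keeps every term its own class;
`stop_tau = Inf` produces a single class).

### GNC and GOLC

`gnc()` processes terms bottom-up by decreasing DAG level (ties broken
lexicographically).  A term with fewer than `lambda` genes hands its genes
to all of its parents and disappears; genes reaching an under-populated
root are reported in the `unplaced` attribute -- this loss is what makes
gene counts vary with `lambda` in practice.  `golc()` re-assigns every
annotation to *all* ancestors at exactly level `iota` (a DAG has multiple
paths, so one annotation may land in several classes); levels are shortest
`is_a` paths from the root, with the root at level 0.

### Classifiers

**MLSVM.**  One soft-margin SVM per class (binary relevance), solved by
libsvm through `e1071`.  The hinge loss of each positive training sample is
amplified by `lambda = N_neg / N_pos`, the inverse class-frequency ratio,
so minority positives are not swamped; negatives keep weight 1.  The kernel
defaults to RBF with bandwidth `1/n_features` and `C = 1`; features are the
preprocessed profiles and are not re-scaled (they share the log-ratio
scale by construction).  Decision values are continuous scores; thresholding
at zero gives labels.

**MLKNN.**  A lazy similarity-sum variant consistent with the pipeline's
correlation geometry: neighbours are found under `1 - r` (ties broken by
sample index), candidate classes are the union of the `k` neighbours' label
sets (`k = 5` by default), each candidate scores the sum of
`(1 + r)/2 in [0, 1]` over its member neighbours, and a class is predicted
when it holds a strict majority of the neighbours' total similarity mass.
With equal similarities this reduces to a majority vote; an exact split
predicts nothing.  The continuous scores feed the ROC analysis directly.

### Evaluation protocol

For a class with `P` positives, a balanced split draws
`floor(n * P + 0.5)` training positives -- halves round up, matching the
reference layout in which 49 positives at `n = 50%` yield 25 training
positives -- clamped to `[1, P-1]` so both sides of the split retain a
positive even for small classes, plus an equal number of uniformly drawn
negatives; everything else is the test set.  AUC is computed by the rank
(Mann-Whitney) formulation with ties counted one half, which the suite
verifies equals both the trapezoidal area under the threshold sweep and a
pairwise brute force.  Class-skipping (fewer than 2 positives, or a
single-class test set) is silent but reported through the detail table.
Per-`n` summaries report the class-then-repetition mean AUC (`mean_auc`)
alongside the pooled mean over all class x repetition cells
(`mean_auc_pooled`); both readings of "average" are legitimate, and the
two coincide when all classes are evaluable in every repetition.
Sub-seeds for each (class, n, repetition) cell are derived deterministically
from the master seed, so runs are bit-for-bit reproducible and repetition
order is immaterial.

## The synthetic generator

`generate_synthetic()` builds a desk-scale stand-in for a yeast cell-cycle
study: by default 4 planted modules x 3 leaf terms x 8 genes plus 20
unannotated background genes, observed at 18 time points on a 7-minute
grid.  Design choices worth knowing:

* **Latent profiles.**  Each module's latent curve is a sinusoid with
  period equal to half the sampled span (about 63 min, i.e. two cycles per
  series).  Modules are assigned to orthogonal harmonic/quadrature pairs
  (`sin`, `cos` of the base frequency, then of the second harmonic, ...)
  with one shared random phase.  Cell-cycle-regulated genes peak at
  characteristic phases, and the orthogonal assignment gives the cleanest
  possible realisation of "distinct expression programmes": between-module
  correlations concentrate near zero instead of scattering over `[-1, 1]`
  as independent random phases would (two modules that draw nearly equal
  phases are genuinely indistinguishable, which would make any evaluation
  of module recovery ill-posed).  A `phase_offsets` override exposes
  arbitrary phase layouts, e.g. exact anti-phase pairs.
* **Noise.**  Gene profiles are the module latent plus i.i.d. Gaussian
  noise (`within_noise_sd = 0.3` log2 units).  The latent amplitude (0.85)
  was fixed once by a pre-build Monte-Carlo against the generator's own
  calibration target -- the clique selection should retain at least 90% of
  planted genes at `alpha = 0.05` while still pruning the worst realisations
  (observed retention: median ~0.97, minimum ~0.93 over 20 seeds).
* **Ontology.**  One root, `n_modules` mid-level terms, and
  `terms_per_module` leaves per module, each leaf annotated with one
  module's genes.  Crucially, each leaf attaches to a *uniformly random*
  mid-level parent.  In the real GO the upper levels group processes
  semantically, not by co-expression; a DAG whose mid terms coincided with
  the planted modules would make up-propagation and expression clustering
  produce identical classes and could not exercise the difference between
  the constructions.  With random attachment, GNC and GOLC classes mix
  modules while MIHC classes follow the expression structure -- the
  contrast the package exists to measure.
* **What is *not* emulated:** array-specific noise (intensity-dependent
  variance, spatial artefacts), missing-value patterns, annotation errors
  (available separately through `perturb_labels()`), overlapping gene
  membership between terms (available via the generator's gene sharing
  being off by default), and realistic GO breadth/depth.  Passing tests on
  this generator therefore demonstrate correctness of the algorithms and
  the expected qualitative ordering of the learning systems, not
  performance on any real organism's data.

## Numerical and degenerate-case conventions

* Constant profiles: correlation is undefined; such pairs are
  non-significant in gene selection, at maximum distance (2) in bag
  distances, and contribute zero similarity in MLKNN.
* Rounding: training-positive counts round halves up (`floor(x + 0.5)`),
  not to even.
* Tie-breaks are everywhere deterministic: lexicographic gene ids in the
  clique heuristic, lowest index pair in merging, lowest sample index in
  neighbour search.
* A class without both a positive and a negative training sample is
  skipped with a warning; its SVM score column is `-Inf` and flagged.
* AUC requires both classes in the truth vector and errors otherwise.
* The trapezoid/rank AUC identity is exact (checked to 1e-12).

## Problem sizes used by the test and acceptance runs

The shipped suite exercises the planted-recovery and system-comparison
properties at the generator's default scale (116 genes, 12 leaf terms, 18
time points) over 20 seeds with 3 protocol repetitions per cell, and the
acceptance script reports medians over 10 seeds; these sizes were chosen
as the smallest at which the between-system contrasts are stable from seed
to seed.  All oracle comparisons (cliques, merges, KNN, AUC) run on
exhaustively checkable sizes (graphs of at most 12 vertices, at most 6
bags, 50 training samples).

## Known limitations

* The greedy clique can under-select genes relative to the exact maximum
  clique; this is inherent to making the selection tractable.
* Bag distances cost `O(|A| x |B|)` correlations per pair; the
  agglomeration is quadratic in the number of terms and is intended for
  hundreds, not tens of thousands, of terms per namespace.
* Only `is_a` edges are read from OBO files; `part_of` and regulatory
  relations are ignored.
* The MLKNN variant is the similarity-sum rule described above, not the
  Bayesian-posterior ML-KNN of the wider literature.
* `mean_tpr`/`mean_fpr` summarise the default operating point only; the
  full ROC comes from the score tables.
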