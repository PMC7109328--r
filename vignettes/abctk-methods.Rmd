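---
title: "Methods: the 188D encoder, the undersampling protocol and the classifier benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 188D encoder, the undersampling protocol and the classifier benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abctk)
```

`abctk` classifies proteins as ABC transporters versus non-transporters from
sequence alone. This vignette documents the model and its assumptions, the
parameters that matter, the numerical conventions the implementation commits
to, what the synthetic generator does and does not emulate, and the known
limitations.

## The 188D feature model

Every sequence is reduced to a fixed 188-dimensional description built from
two ingredients.

**Amino-acid composition (20 features).** The frequency of each residue,
`n_k / L`. We freeze the order as alphabetical one-letter codes
(ACDEFGHIKLMNPQRSTVWY); any fixed order is equivalent as long as it never
changes, and `feature_names()` / `feature_descriptions()` expose the frozen
layout (guarded by a golden-file test).

**Physicochemical descriptors (8 × 21 = 168 features).** Each of eight
attributes — hydrophobicity, normalized van der Waals volume, polarity,
polarizability, charge, surface tension, secondary structure, solvent
accessibility — partitions the 20 residues into three classes
(`property_schemes()`); for example charge splits the alphabet into KR
(positive), DE (negative) and the 16 neutral residues. Per attribute the
encoder emits:

- *composition*: the three class fractions (sum to 1);
- *distribution*: for each class, the normalized positions of the first
  occurrence and of the 25/50/75/100 % occurrence percentiles;
- *transition*: the frequencies of adjacent pairs whose classes differ,
  one feature per unordered class pair, denominator `L - 1`.

All 188 entries lie in [0, 1], so no further scaling is needed for
distance-based consumers (k-NN, t-SNE); the SVM additionally standardizes
features internally as is conventional for margin methods.

### Numerical conventions

Three conventions are genuinely open in this descriptor family, and the
implementation commits to one reading of each:

- **Distribution percentiles are over class occurrences, not raw chain
  positions**: with `m` occurrences at positions `p_1 < … < p_m`, the entry
  for quantile `q` is `p_r / L` with `r = ceiling(q m)`, and the first anchor
  is `p_1 / L`. This is the established convention of the
  composition/transition/distribution descriptor family; the alternative
  reading ("fixed fractions of the chain length") would make the five
  anchors redundant with composition. Custom schemes can be supplied via
  `read_schemes()` if a user wants to experiment with other partitions.
- **A class with no occurrence contributes five zeros.** Zeros keep every
  feature in [0, 1] and make absence distinguishable from presence at the
  N-terminus only through the composition block, which carries the same
  information anyway.
- **Transitions are unordered between-class pairs** ({1,2}, {1,3}, {2,3}):
  only this reading yields exactly three features per attribute and hence
  the 3 + 3 + 15 = 21 per-attribute count that makes 188 in total.

Because no published worked feature vector exists for this encoding, the
test suite instead proves the implementation equal (to 1e-12) to an
independently written brute-force oracle encoder on 200 random sequences,
alongside hand-derived small cases and invariance properties (reversal
preserves composition; all normalization identities).

Sequences must be at least 2 residues long (the transition denominator), and
residues outside the 20-letter alphabet (B, Z, X, U, O, J) are handled by a
configurable policy, default *drop-residue*; the formulas are only defined on
the canonical alphabet and curated databases rarely contain more than a
handful of ambiguous positions, so dropping individual characters preserves
more data than rejecting whole sequences. The alternative *reject-sequence*
policy is available for stricter curation.

## Dataset protocol

**Redundancy reduction** (`reduce_redundancy()`, threshold 0.6) uses greedy
incremental clustering in descending length order, the CD-HIT scheme. The
built-in identity measure is deliberately simple: candidate pairs must share
at least one 3-mer, and identity is the best ungapped-offset match count
divided by the shorter length. This is an approximation — it has no gapped
alignment and no banded search — and is documented as such; an installed
CD-HIT binary can be used instead (`method = "cdhit"`) when exact behaviour
is required. The filter is deterministic, never grows its input, and is
idempotent.

**Repeated balanced undersampling** (`make_balanced_splits()`) addresses the
heavy class imbalance of transporter pools (here 875 positives against 9736
negatives after redundancy reduction): each of 10 repetitions draws 875
negatives without replacement to join all positives (training set of 1750),
and the remaining 8861 negatives form the repetition's test set. Two
consequences are worth making explicit:

- the held-out sets contain **only negatives**, so hold-out "accuracy" is
  specificity on unseen negatives; `evaluate_holdout()` flags SN, MCC and
  AUC as undefined on single-class data rather than reporting misleading
  numbers. Mixed test sets, when supplied, yield the full panel, clearly
  labelled by the report's `level`.
- results must be aggregated across the 10 repetitions;
  `aggregate_reports()` uses sample-count-weighted means and retains
  per-split values for dispersion.

Every repetition uses an independent sub-seed derived deterministically from
the master seed and the repetition index (an affine mix modulo a prime below
2^31), recorded in each split manifest, so a fixed seed reproduces the entire
protocol byte-for-byte.

## Classifier benchmark

Five families are exposed through one contract (`classifier_spec()` →
`fit_classifier()` → `predict()`), with defaults chosen to mirror a
Weka-style benchmark environment:

| family | backend | defaults | rationale |
|---|---|---|---|
| `random_forest` | randomForest | 100 trees, `floor(log2(188)) + 1 = 8` features/split | common forest defaults for ~190 features |
| `c45_tree` | rpart, information split | `minbucket = 2`, `cp = 0.01` | C4.5 approximation; exact error-based pruning is out of scope |
| `naive_bayes` | e1071 | Gaussian class-conditionals | features are continuous; no discretization assumed |
| `svm` | e1071 | linear kernel, `C = 1`, standardized features | high-dimensional, near-linearly-separable encodings |
| `knn` | class | `k = 1` | the classical instance-based default |

Evaluation is stratified k-fold cross-validation (default 10): fold class
proportions deviate from the global ratio by at most one sample, folds are
assigned from a derived seed, each fold's model is fitted with its own
derived seed, and confusion counts plus probability scores are pooled over
folds. ACC, SN, SP and MCC follow the standard confusion-matrix formulas
with the square-root MCC denominator; any metric with a zero denominator is
reported as 0 with an explicit `undefined` flag so multi-split aggregation
never aborts. ROC curves sweep descending unique scores with ties grouped
into a single step; the trapezoidal AUC then equals the Mann-Whitney
probability estimate, which the tests verify to 1e-12 (and cross-check
against pROC). An optional small grid search (`tune_classifier()`) selects
hyperparameters inside CV; the default grids are listed in its help page.

## Exact t-SNE

`tsne_embed()` implements exact (non-Barnes-Hut) t-SNE: perplexity-calibrated
Gaussian input similarities (binary search per point), a Student-t kernel in
the embedding, and gradient descent with momentum (0.5 then 0.8), adaptive
gains, learning rate 200, and early exaggeration. The benchmark settings are
`dims = 2, perplexity = 10, theta = 0, max_iter = 1000,
exaggeration_factor = 8`; `theta` must be 0 because only the exact gradient
is implemented, which is entirely adequate at the few hundred points a
visualization uses. The early-exaggeration *duration* (250 iterations) and
the momentum switch point are solver conventions, stated here as assumptions
since only the factor itself is part of the benchmark settings. The seed is
a required, echoed parameter (default 42). Features are embedded raw by
default — they already live in [0, 1] — with standardization available as a
flag.

Embeddings are rotation- and translation-arbitrary, so all assertions about
them use label-relative statistics only: mean silhouette against class
labels and k = 10 neighbor label purity compared against permuted labels.

## The synthetic generator

`generate_dataset()` emulates the one property of the real curated dataset
the encoder provably responds to: a class-wise amino-acid composition bias.
Negatives are i.i.d. uniform over the 20 letters (a natural-frequency
background is available); positives raise the total probability of a biased
residue set — default CVLIMFW, the hydrophobic class of the hydrophobicity
partition, so the signal is visible to the encoder by construction — by an
effect size `delta`, renormalized. `delta = 0` makes the classes
exchangeable, giving a null calibration; classification power is monotone in
`delta` (verified for RF accuracy over delta 0/0.1/0.3 averaged over 5
seeds). Default sizes (875/9736) mirror the curated pool's scale so the
split protocol's structural counts (1750-sample training sets, 8861-negative
test sets) are exercised as-is; default lengths are uniform on 100–400
residues, a realistic range for the cytoplasmic-domain-scale sequences this
kind of benchmark uses while keeping encoding fast.

What the generator does **not** emulate: domain architecture (NBD/TMD
motifs), positional signal of any kind, phylogenetic correlation between
sequences, and length differences between classes. Passing tests on
synthetic data therefore demonstrate that the pipeline's machinery is
correct and well-calibrated — they say nothing about attainable accuracy on
real transporter data, which depends on the curated external dataset.
Near-perfect synthetic benchmark numbers reflect the deliberately strong
default bias, not expected real-world performance.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the protocol at the sizes the
method defines where those are structural (875/9736 pool, 10 repetitions,
10-fold CV, 1750-sample training sets), and at moderate sizes where the
check is statistical: power calibration at 500 + 500 sequences over 5 seeds,
embeddings of 200 points, and a miniature end-to-end pipeline for the
byte-identical-rerun check. These sizes were chosen as the smallest at which
the statistical assertions are stable across seeds.

## Known limitations

- The built-in redundancy filter is an ungapped approximation of CD-HIT;
  identity near the threshold can differ from CD-HIT's banded alignment.
- `c45_tree` approximates C4.5 (entropy splits, minimum-leaf pruning); it is
  not bit-compatible with Weka's J48, nor is the SVM with SMO.
- Exact t-SNE is O(n²) per iteration; embed a subsample (as
  `run_pipeline()` does, default 200 points) rather than tens of thousands
  of sequences.
- With `k = 1`, k-NN scores are 0/1, so its ROC has a single interior point;
  AUC is still well-defined but coarse.
- The encoder is composition-based: it cannot represent positional motifs,
  and two sequences with equal class compositions and similar occurrence
  quantiles are nearly indistinguishable to it.
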