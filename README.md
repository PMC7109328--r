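# abctk

Sequence-based identification of ATP-binding cassette (ABC) transporters.

ABC transporters are membrane proteins that hydrolyze ATP to move molecules
across membranes; they import nutrients in bacteria, traffic metabolites in
plants, and drive multidrug resistance in cancer cells. Annotating them by
homology search (BLAST, HMMER) is slow and misses divergent family members,
so `abctk` implements the machine-learning alternative: classify a protein as
ABC transporter / non-transporter directly from its sequence.

The package is aimed at bioinformaticians who have a curated positive set and
a large negative pool in FASTA and want a reproducible, fully scripted
benchmark of sequence-feature classifiers — plus a synthetic-data generator
so every stage can be exercised and tested without any downloads.

## Method

**188D feature encoding.** Each sequence of length *L* is mapped to 188
features. The first 20 are the amino-acid composition frequencies
*F₁…F₂₀ = n₁/L, …, n₂₀/L*. The remaining 168 come from eight three-class
physicochemical partitions of the alphabet (hydrophobicity, normalized van
der Waals volume, polarity, polarizability, charge, surface tension,
secondary structure, solvent accessibility). For each partition the encoder
computes, per class *i*:

- **Composition** — CSᵢ/L, the fraction of residues in class *i* (3 features);
- **Distribution** — DSᵢⱼ/L for j = 1…5, the normalized chain positions of
  the first occurrence and of the 25 %, 50 %, 75 % and 100 % occurrence
  percentiles of class *i* (15 features);
- **Transition** — BSₖ/(L−1), the frequencies of adjacent residue pairs whose
  classes differ, for the unordered pairs {1,2}, {1,3}, {2,3} (3 features);

giving 3 + 15 + 3 = 21 features per partition and 20 + 8 × 21 = 188 in total,
all in [0, 1].

**Dataset protocol.** Redundancy is removed with a greedy identity filter at
threshold 0.6 (or an external CD-HIT binary). The imbalanced pool is then
balanced by repeated random undersampling: each of 10 repetitions draws as
many negatives as there are positives for the training set, and the left-over
negatives form that repetition's held-out test set.

**Benchmark.** Five classifier families — random forest, an entropy-split
decision tree (C4.5-like), Gaussian naive Bayes, a linear SVM and k-nearest
neighbours — are compared under seeded, stratified 10-fold cross-validation,
reporting ACC, SN, SP, MCC = (TP·TN − FP·FN)/√((TP+FN)(TP+FP)(TN+FP)(TN+FN)),
ROC curves and AUC, with results aggregated across the 10 balanced splits by
sample-weighted averaging. Feature matrices can also be projected to 2-D with
an exact (theta = 0) t-SNE implementation for visual inspection.

## Worked example

```r
library(abctk)

pool   <- generate_dataset(synthetic_spec(n_positive = 100, n_negative = 400,
                                          length_range = c(100, 400),
                                          delta = 0.3, seed = 1))
splits <- make_balanced_splits(pool, repeats = 10, seed = 1)
splits[[1]]
#> balanced_split 1 (seed 65079): train 200 (100+/100-), test 300 negatives

fm <- encode_dataset(splits[[1]]$train)
fm
#> feature_matrix: 200 sequences x 188 features
#> labels: negative=100, positive=100

report <- cross_validate(fm, classifier_spec("random_forest", seed = 1),
                         folds = 10, seed = 1)
report
#> evaluation_report [random_forest, split] on 200 samples
#>   ACC 1  SN 1  SP 1  MCC 1  AUC 1

emb <- tsne_embed(fm, perplexity = 10, theta = 0, max_iter = 1000,
                  exaggeration_factor = 8, seed = 42)
round(embedding_silhouette(emb), 2)
#> [1] 0.81
```

The synthetic positives here carry a composition bias of `delta = 0.3` on the
hydrophobic residues CVLIMFW, a signal the 188D encoder captures by
construction — hence the perfect cross-validated metrics (ACC/SN/SP/MCC of 1
mean every held-out fold sample was classified correctly) and the strong
class separation in the embedding (mean silhouette 0.81, where 0 would mean
no separation). At `delta = 0` the same pipeline returns chance-level AUC
near 0.5.

For real data, replace the generator with FASTA input:

```r
pool <- sample_pool(read_fasta("positives.fasta", "positive"),
                    read_fasta("negatives.fasta", "negative"))
pool <- sample_pool(reduce_redundancy(pool$positives, 0.6),
                    reduce_redundancy(pool$negatives, 0.6))
```

An end-to-end run (`run_pipeline()`, or the CLI at `inst/cli/abctk.R` with
subcommands `simulate`, `encode`, `reduce`, `split`, `train`, `evaluate`,
`embed`, `run-all`) writes split manifests, the feature matrix, per-split
CV and hold-out reports, the embedding, and a manifest with seeds and MD5
checksums; rerunning the same configuration reproduces the manifest
byte-for-byte.

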