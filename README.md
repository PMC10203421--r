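# tissuespec

Identification of **tissue-specific genes** from a multi-tissue bulk
RNA-seq compendium — a samples × genes TPM matrix with a tissue label per
sample — using three model families with different inductive biases, plus
a clustering-based referee that decides which candidate gene set carries
the most tissue structure.

Who it is for: anyone mining a public expression compendium (plant or
otherwise) for marker genes, and anyone comparing linear, tree-ensemble
and neural strategies for the same selection problem on a common footing.

## What it computes

**Linear track** — per tissue pair, empirical-Bayes moderated-t
differential expression on log2(TPM+1):

```
s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g),   t_g = logFC_g / (s̃_g √(1/n_A + 1/n_B))
```

with (d₀, s₀²) estimated by log-variance moment matching (trigamma
inversion). Genes with `adj.P.Val < 0.01` and `|logFC| > 4` (BH-adjusted,
strict) are collected and unioned over all tissue pairs.

**Tree track** — SMOTE class balancing, stratified 10-fold cross-validated
gradient-boosted classification, then shadow-feature filtering: every gene
column is permuted into a "shadow", a booster is trained on
`[real | shadow]`, and across repetitions each feature gets
`Z = mean(gain)/sd(gain)`. A gene is kept iff `Z_real > Z_max`, the
largest shadow Z.

**Neural track** — each sample's expression vector is zero-padded into a
square image (21,111 genes → 146×146); a CNN of 3×3-conv/ReLU/BatchNorm
blocks with max pooling and a softmax head is trained with RMSprop on the
categorical cross-entropy `−Σ yᵢ log ŷᵢ`. Correctly predicted samples are
explained by expected-gradients attribution of the true-class score;
per-tissue median attributions are ranked, the top 1% per tissue kept, and
the per-tissue top halves unioned.

**Validation** — k-means clustering of samples restricted to each gene
set, scored by the V-measure (harmonic mean of entropy-based homogeneity
and completeness) and tested against 100 size-matched random gene sets
with a one-tailed predictive t-test. The intersection of all tracks is the
core set.

A synthetic generator plants disjoint marker genes per tissue at a known
log2 effect size inside a log-normal TPM background (with a rare tissue
and a discardable "mixed" tissue), so every stage is testable against
ground truth without any downloads.

## Worked example

```r
library(tissuespec)

sim <- generate_expression(synth_config(seed = 1))   # 95 samples x 2000 genes
table(sim$annotation$tissue)
#>     leaf    mixed     root     seed seedling
#>       30        8       25       20       12

pp   <- filter_samples(sim$matrix, sim$annotation,
                       min_per_tissue = 10, drop_labels = "mixed")
logm <- log2_transform(filter_genes(pp$matrix, tpm_threshold = 1))  # 87 x 2000

de <- de_track(logm, pp$annotation)        # moderated t, BH < 0.01, |logFC| > 4
de$counts
#>               pair total up down
#> 1     leaf.vs.root   100 50   50
#> 2     leaf.vs.seed   100 50   50
#> 3 leaf.vs.seedling   100 50   50
#> 4     root.vs.seed   100 50   50
#> 5 root.vs.seedling   100 50   50
#> 6 seed.vs.seedling   100 50   50

retained <- geneset(unlist(sim$truth$planted[unique(pp$annotation$tissue)]), "truth")
set_recovery(de$geneset, retained)
#> precision    recall     n_set   n_truth
#>         1         1       200       200

br  <- boruta_filter(logm, pp$annotation, n_reps = 10, seed = 1)  # 142 genes kept
cnn <- cnn_track(logm, pp$annotation, config = cnn_config(seed = 1))  # 40 genes

evaluate_all(logm, pp$annotation,
             list(limma = de$geneset, lgbm = br$geneset, cnn = cnn$geneset),
             n_runs = 10, n_null_sets = 50, seed = 1)
#> <cluster_eval_report> sets ranked by mean V-measure
#>     set size mean_v p_value provenance
#> 1   cnn   40 0.9345  0.1710        cnn
#> 2  full 2000 0.9312  0.3558       full
#> 3 limma  200 0.8951  0.2840      limma
#> 4  lgbm  142 0.8164  0.7844       lgbm

core_intersection(list(de$geneset, br$geneset, cnn$geneset))
#> <geneset> 31 genes, provenance 'core'
```

Reading the numbers: all 200 planted markers of the retained tissues are
recovered by the linear track with no false positives; the CNN's compact
40-gene set clusters the samples as well as the full 2,000-gene matrix.
The p-values compare each set against size-matched random draws — at this
low noise level random draws also contain enough markers to cluster well,
a saturation effect discussed in the methods vignette. `run_pipeline()`
wires the same stages together from one (YAML-able) configuration and
writes every artifact plus a `provenance.json` of parameters and seeds.

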