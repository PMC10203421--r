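---
title: "Identifying tissue-specific genes with three model families"
author: "tissuespec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying tissue-specific genes with three model families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuespec)
```

## The problem

A tissue-specific gene is one whose expression is preferential in one or a
few tissues. Given a bulk RNA-seq compendium — a samples x genes TPM matrix
with a tissue label per sample — the package identifies such genes with
three model families whose inductive biases differ, then asks a neutral
referee which candidate set best separates tissues:

* **linear track** (`de_track()`): pairwise differential expression with an
  empirical-Bayes moderated t-statistic; a gene is tissue-specific if it is
  strongly differential in some tissue pair.
* **tree track** (`boruta_filter()`): a gradient-boosted tree classifier of
  tissue labels; a gene is tissue-specific if its split-gain importance
  reliably beats permuted "shadow" copies of the genes.
* **neural track** (`cnn_track()`): a convolutional network classifies
  samples from their expression rendered as a square image; a gene is
  tissue-specific if gradient attributions credit it for correct
  predictions.
* **validation** (`evaluate_all()`): k-means clustering of samples
  restricted to each candidate set, scored by the V-measure against the
  true labels and compared with size-matched random gene sets.

Public compendia are messy in predictable ways — rare tissues, a "mixed"
tissue, low-expression genes — so preprocessing (`filter_samples()`,
`filter_genes()`, `log2_transform()`) reproduces the standard cleaning
steps, and a synthetic generator (`generate_expression()`) provides ground
truth to test every stage.

## The synthetic generator

`generate_expression()` draws log2 expression as

$$\log_2 x_{sg} = b_g + \delta\,[g \text{ planted for tissue}(s)] + \varepsilon_{sg},$$

with a per-gene baseline $b_g \sim N(\mu_b, \sigma_b^2)$ drawn once,
a planted shift $\delta$ (`effect_size`, default 6) applied only in the
marker's home tissue, and noise $\varepsilon_{sg} \sim N(0, \sigma^2)$
(`noise_sd`, default 0.3). Values are exponentiated and each sample is
scaled to sum to $10^6$, the TPM contract. Planted sets are pairwise
disjoint, `planted_per_tissue` per tissue (default 50 of 2,000 genes).

The default tissue layout mimics a database situation: five labels with
sizes 30/25/20/12/8, where the 8-sample "mixed" tissue is discarded by
preprocessing and the 12-sample "seedling" survives as a rare class that
exercises rebalancing. All randomness flows from the single `seed` field;
the same configuration is bitwise reproducible.

Two properties of real data the generator deliberately reproduces, and one
it does not:

* **Compositional coupling.** Because TPM renormalizes each sample, one
  tissue's markers contribute tissue-specific library mass; the pairwise
  logFC of a marker therefore deviates from the nominal $\delta$ by the
  between-tissue mass ratio. With 2,000 genes and 50 markers per tissue the
  deviation is small (the empirical home-vs-other contrast at $\delta = 6$
  is within $6 \pm 0.5$), but with very few genes it is visible. This is a
  feature: real TPM matrices behave the same way.
* **Class imbalance**, including a below-cutoff tissue, per the default
  layout above.
* **Not modeled:** batch effects, count-level (negative binomial)
  sampling, or read-level artifacts. A pass on synthetic data therefore
  demonstrates correct mechanics and sensible statistical behavior, not
  robustness to batch structure.

## Linear track: moderated t

For a tissue pair $(A, B)$ on $\log_2(\mathrm{TPM}+1)$ values, each gene
gets $\mathrm{logFC} = \bar x_A - \bar x_B$ and a pooled two-group variance
$s_g^2$ with $d_g = n_A + n_B - 2$ df. Variances are shrunk toward a prior
estimated from all genes by matching the mean and variance of
$\log s_g^2$ to scaled log-F moments (trigamma inversion):

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\mathrm{logFC}_g}{\tilde s_g \sqrt{1/n_A + 1/n_B}},$$

with $d_0 + d_g$ df. This is exactly the computation a standard
empirical-Bayes DE fit performs for a two-group contrast, and the test
suite verifies agreement with limma's `lmFit()`/`eBayes()` to $10^{-10}$
on both the finite-$d_0$ and $d_0 = \infty$ branches. One boundary is
worth knowing: when all $s_g^2$ are identical, the moment estimator
returns $d_0 = \infty$ with the bias-corrected prior
$\exp(\overline{\log s^2} - \psi(d/2) + \log(d/2))$, which differs from
the raw $s_g^2$ by the mean of $\log \chi^2_d/d$ — the estimator is
inverting the expected downward bias of a log sample variance, again
matching limma.

Genes pass with `adj.P.Val < 0.01` and `|logFC| > 4` (both strict), BH
adjusted; the sign files them as up or down. Per-pair sets are merged as a
deduplicated **union** across all tissue pairs. An intersection would be
nearly empty whenever one pair is near-silent (closely related tissues
routinely yield a handful of DEGs), which is why union is the default;
`merge_pair_sets(combine = "intersection")` exposes the alternative.

## Tree track: shadow-feature filtering

`train_gbm_cv()` reports stratified 10-fold cross-validation metrics
(accuracy, macro one-vs-rest AUC, macro recall/precision/F1, Cohen's
kappa) and fits a final booster on a stratified 70/30 split. Class
imbalance is corrected first by `balance_classes()`, a SMOTE
implementation: every synthetic minority sample is
$x_i + u\,(x_j - x_i)$, $u \sim U(0,1)$, with $x_j$ one of the $k$ nearest
same-class neighbors; originals are never modified.

The selection logic is `boruta_filter()`. Each repetition permutes every
gene column independently (shadows), trains a booster on
`[real | shadow]`, and records per-feature total split gain. Across
`n_reps` (default 20) repetitions each feature gets
$Z = \bar g / \mathrm{sd}(g)$, and a real gene is kept iff
$Z_{\mathrm{real}} > Z_{\max} = \max Z_{\mathrm{shadow}}$. Conventions and
numerical choices:

* A feature with zero importance SD has $Z = +\infty$ if its mean gain is
  positive and $-\infty$ otherwise, so constant or never-used genes can
  never be kept. `n_reps < 2` is an error (the SD is undefined).
* Split gain is the importance measure (the information-gain reading of
  tree importances); `information_gain()` provides the base-2 entropy
  definition itself, tested against exhaustive enumeration.
* The booster defaults (depth 4, learning rate 0.2, 50 rounds,
  row subsample 0.8, **per-node** column subsample 0.1) are a documented
  fixed choice, overridable via `params=`. Per-node column subsampling
  matters scientifically: tissue markers are interchangeable within a
  tissue, and without it the booster credits one or two genes per tissue
  and the rest never accumulate importance.
* Repetitions redraw shadows and booster subsampling; the Z statistics are
  taken **across repetitions**, the only reading under which an SD exists
  for single-model gain scores.
* Internally genes are processed in sorted-ID order: greedy tree learners
  break exact gain ties by column position, and the canonical order makes
  the kept set invariant to the caller's column order.
* Scale matters for the shadow yardstick. On the 2,000-gene reference
  fixture the filter keeps a set that is >95% planted and keeps under 3%
  of genes when no signal exists; on toy matrices with tens of samples and
  hundreds of genes, chance-correlated background genes can pass, so the
  purity figures quoted here are statements about the reference scale.

## Neural track: expression images and attribution

`squarify(n)` returns the smallest $s$ with $s^2 \ge n$;
`reshape_samples()` lays genes row-major into an $s \times s$ one-channel
image with zero padding (21,111 genes give $146 \times 146$) and keeps the
exact gene-to-pixel map. The network is a stack of ConvBlocks
(3x3 convolution, ReLU, BatchNorm), each followed by 2x2 max pooling, then
a dense layer and a softmax head, trained with RMSprop on the categorical
cross-entropy $-\sum_i y_i \log \hat y_i$ (natural log; the base only
scales the loss). The engine — im2col convolution, BatchNorm in train and
eval modes, pooling with first-match tie-broken gradients, RMSprop with
$lr/(1 + \mathrm{decay}\,t)$ — is implemented in the package and verified
against numeric differentiation.

Two profiles exist: `cnn_config()` (two 8/16-filter blocks, batch 16,
20 epochs, learning rate $10^{-3}$) suits few-thousand-gene fixtures on
one CPU; `cnn_config_full()` (32/64/128 filters, batch 64, 50 epochs,
learning rate $10^{-4}$, rho 0.9, decay 0.01) is the training profile for
~20,000-gene matrices. The desk profile's larger learning rate simply
compensates for the far smaller number of updates.

`attribute()` explains only **correctly predicted** samples and only the
true-class score. The default is expected gradients,
$\mathbb{E}_{b,\alpha}\big[(x - b)\odot\nabla f_c(b + \alpha(x-b))\big]$
over a background of reference images; `"gradxinput"`
($x \odot \nabla f_c(x)$) is the cheap fallback and is exact for a linear
model (a property the tests check). Pixel attributions map back to genes;
padding is discarded. Per tissue, the median attribution per gene is
ranked and the top 1% kept (minimum one gene, ties broken by gene ID);
`combine_tissue_lists()` then keeps the top half of each tissue's list and
takes the deduplicated union. A strict multi-tissue intersection is
available but empties quickly as tissues disagree, so union is the
default.

## Validation: V-measure against a resampling null

`vmeasure()` computes, with natural-log entropies (the base cancels),
homogeneity $h = 1 - H(C|K)/H(C)$, completeness $c = 1 - H(K|C)/H(K)$ and
their harmonic mean $v$; $h = 1$ when $H(C) = 0$, $c = 1$ when
$H(K) = 0$, $v = 0$ when $h + c = 0$. `cluster_with_geneset()` restricts
the matrix to a gene set and runs Lloyd's k-means `n_runs` times (default
10) with fresh random initializations, retrying an initialization that
leaves a cluster empty; `k` defaults to the number of tissue labels.

`null_distribution()` scores `n_sets` (default 100) uniformly drawn gene
sets of the same size. `one_tail_test()` then uses the predictive t

$$t = \frac{\overline{V}_{\mathrm{null}} - V_{\mathrm{cand}}}
          {s_{\mathrm{null}}\sqrt{1 + 1/n}},\quad df = n - 1 .$$

The $\sqrt{1 + 1/n}$ is deliberate: the candidate's mean V is one more
draw from the same population, not a fixed constant, so the plain
one-sample scaling $s/\sqrt{n}$ would concentrate p-values at 0 and 1.
With the predictive scaling the p-value is uniform when the candidate is
itself a random set — the property the calibration test checks with a
Kolmogorov–Smirnov test over 200 replicates — while a candidate far above
the null still gets a vanishing p-value. A degenerate null
($s_{\mathrm{null}} = 0$) returns 0, 1 or 0.5 by convention.

One saturation effect matters when interpreting these comparisons: if
markers are strong and background noise is low, a size-matched random set
already contains enough markers (about 10% of a 200-gene draw on the
reference fixture) to cluster tissues almost perfectly, and candidate and
null distributions collapse onto each other near $V = 1$. The package's
validation fixture therefore uses heavy background noise
(`noise_sd = 3` against effect 6), where a coherent marker panel clearly
beats diluted random panels. On real compendia the same caveat applies:
a non-significant null test can mean "everything clusters well", not
"the candidate is poor".

`core_intersection()` reports the genes all tracks agree on.

## Problem sizes and budgets

The reference fixture used throughout the tests and the acceptance script
is 4 tissues x 20 samples, 2,000 genes, 50 planted markers per tissue
(effect 6, noise 0.3); unit tests use a 3-tissue, 300-gene variant;
calibration uses 60 samples x 300 genes with no signal. These sizes make
the whole suite run in minutes on one CPU while leaving every stage's
behavior measurable. The full pipeline (`run_pipeline()`) on the default
synthetic configuration completes in well under 15 minutes on one CPU, and
rerunning it with the same configuration reproduces every gene set and
report value exactly.

## Known limitations

* No batch-effect or count-level model in the generator; conclusions about
  robustness to those must come from real data.
* The moderated-t track covers two-group contrasts only — no design
  matrices, variance trends, or robust estimation.
* The tree track's shadow yardstick is permissive on very small matrices.
* The CNN engine is plain R; it is comfortable at desk scale and
  correctness-checked, but a framework-backed implementation would be
  preferred for paper-scale (146 x 146, 50-epoch) training time.
* k-means with random initialization is the clustering referee by design;
  its initialization noise is averaged over `n_runs`, not eliminated.
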