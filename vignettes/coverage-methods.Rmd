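---
title: "Coverage-based multiclass DEG discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based multiclass DEG discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covDEG)
```

# Overview

`covDEG` implements a multiclass biomarker-discovery pipeline for
integrated gene-expression studies: per-series quality screening,
merging and joint quantile normalization of heterogeneous series, DEG
extraction with a pairwise-contrast *coverage* statistic on top of
empirical-Bayes moderated t-tests, mRMR feature ranking, and a
cross-validation harness with a factorial ANOVA over the pipeline's own
hyperparameters. This vignette documents the statistical models, the
defaults and why they were chosen, the numerical conventions, and what
the synthetic validation data can and cannot show.

# The data model

The central container, `CovExperiment`, extends
`SummarizedExperiment`: a genes-by-samples matrix of **log2-scale**
expression values with two per-sample annotations, a disease-state
class (e.g. HBM/AML/ALL/CML/CLL) and a series (batch/platform)
identifier. Values are assumed to be already preprocessed and
log-transformed; the package applies no background correction or probe
summarization, and takes gene-level matrices as given. Empty matrices,
duplicate identifiers and non-finite values are rejected at
construction, because every downstream stage assumes at least one gene
and fully observed data.

# Quality screening

For each series separately, each sample's expression distribution is
compared with the pooled distribution of all samples in that series via
the exact two-sample Kolmogorov–Smirnov sup-distance $K_a$ (the tested
sample is included in the pool by default; `excludeSelf = TRUE` gives
leave-one-out pooling). Samples are flagged when
$K_a > Q_3 + 1.5\,\mathrm{IQR}$ of the per-series $K_a$ values. The
boxplot fence was chosen because it is scale-free: $K_a$ values
concentrate differently depending on gene count and sample count, so a
fixed cut-off would not transfer across series. The fence multiplier is
configurable. The screen runs per series, before merging, because a
batch offset that the later normalization removes would otherwise
dominate the statistic.

The rule has the usual boxplot-rule property of occasionally flagging a
borderline sample in clean data (the fence adapts to the observed
spread, which is tight for null data). In the full chain this is
harmless — a dropped clean sample barely moves class means with dozens
of samples per class — but it is the reason the screen is reported, not
silently applied.

# Integration

Merging intersects gene sets (first matrix's order, samples
concatenated); missing genes are dropped, never imputed, so
normalization never sees missing values. Joint quantile normalization
maps every column onto the reference distribution defined as the
row-wise mean of the column-sorted matrix. Two conventions matter:

* the sorted value vector of every column is afterwards *identical*
  (exact equality, not approximate), which makes the "same empirical
  distribution across samples" contract testable as an invariant;
* tied values within a column receive the mean of the reference
  quantiles they span (the standard tie rule).

The transformation preserves each column's rank order, is idempotent,
and removes any per-series affine (offset + scale) or monotone
distortion. Because the inputs here are single-intensity gene-level
matrices, the A-value/M-value distinction that arises for two-color
arrays collapses to ordinary single-channel quantile normalization.
The pipeline order is fixed as QC → merge → normalize.

# Multiclass model, moderation and coverage

For gene $g$ with class means $\mu_{gc}$ and pooled within-class
variance $s_g^2$ on $d = n - N$ degrees of freedom, the
empirical-Bayes prior $(d_0, s_0^2)$ is estimated by matching the first
two moments of $\log s_g^2$ to its theoretical scaled-F distribution
via digamma/trigamma relations; the trigamma inverse is solved by
Newton iteration (relative tolerance $10^{-8}$, at most 50 iterations).
When the observed log-variances show no excess dispersion the prior
degrees of freedom are infinite and every posterior variance equals the
mean observed variance. The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ always lies between
$s_g^2$ and $s_0^2$ (monotone shrinkage); $d_0 = 0$ disables moderation
exactly, which is also the bridge to the classical pooled two-sample
t-test used as an oracle in the tests.

All $(N^2-N)/2$ unordered pairwise contrasts are computed from one fit.
A gene's coverage is the number of pairs passing *both* the
$|\mathrm{LFC}|$ and the p-value gate. Conventions:

* the p-value gate is **raw** by default (the selection rule is stated
  on unadjusted p-values); per-pair Benjamini–Hochberg adjustment is
  available via `adjust = "BH"` for users who want FDR control;
* the per-gene summary columns of the DEG table (mean $|t|$, mean $p$,
  mean $|\mathrm{LFC}|$) average over the **covered pairs only**.
  Averaging over all pairs would dilute a gene's statistics with the
  comparisons it does not discriminate, which is precisely what
  coverage is designed to separate; this was a genuinely open choice
  and is recorded here as the package's convention;
* output ordering is COV descending, then mean $|t|$ descending, then
  gene id — fully deterministic;
* degenerate noise-free inputs (zero posterior variance) are guarded by
  flooring the variance at machine epsilon, and p-values are floored at
  the smallest positive double so the $(0, 1]$ contract holds.

# mRMR ranking

Expression of the selected DEGs is first scaled per gene to median 0 /
sd 1, then discretized into three states at mean $\pm k_\sigma$ sd
(default $k_\sigma = 1$ — the canonical three-level discretization for
continuous expression; the procedure is invariant to per-gene affine
transforms). Relevance and redundancy are plug-in mutual informations
(base 2) on this discretization, the class variable entering as-is. The
greedy criterion is the MID *difference* scheme
$I(g;\mathrm{class}) - \frac{1}{|S|}\sum_{s \in S} I(g;s)$, matching an
additive "maximum relevance, minimum redundancy" reading; ties at any
step break lexicographically by gene id so rankings are reproducible.
The implementation is checked against an independently coded
brute-force greedy oracle for exact sequence equality.

# Cross-validation harness

Stratified k-fold assignment (default $k = 5$) shuffles within class
and deals round-robin, keeping each fold's per-class count within one
of $n_c/k$ — important for the small classes (HBM 26, CLL 29) of the
unbalanced five-class design. Within each fold, the median/sd scaling
statistics are computed on the **training fold only** and applied to
the test fold; a pure-noise "leakage canary" (which must stay at chance
accuracy) guards this in the tests. Out-of-fold predictions are pooled
into one confusion matrix before computing accuracy and F1, which is
stabler for small classes than averaging per-fold metrics (per-fold
values are reported too).

The F1 score is **macro-averaged** by default (unweighted over classes,
0 where precision + recall is 0): with class sizes this unbalanced, the
micro average would be dominated by the large classes and reduce to
accuracy. Micro is available by flag. Classifier defaults — RBF-kernel
SVM with one-vs-one voting, k-NN with $k = 3$, Gaussian naive Bayes,
random forest with 100 seeded trees — are harness conventions, not
tuned claims; all are configurable. The classifiers themselves are the
established e1071/class/randomForest implementations; the harness,
folding, metrics and ANOVA are implemented in the package.

# Factorial ANOVA

`factorialAnova` fits the main-effects linear model of a response
(accuracy or F1) on the experiment factors under sum-to-zero coding and
attributes to each factor its Type III sum of squares by comparing the
full model with the model excluding that factor. For balanced grids
this equals sequential SS (checked against a closed-form oracle); for
unbalanced tables it is the marginal attribution. Conventions: a
constant response (up to a rounding tolerance of $10^{-12}$ relative to
the response scale) reports all SS 0, $F = 0$, $p = 1$; rank-deficient
designs raise an error naming the aliased terms.

# The synthetic-data generator

`simulateDataset` generates
$x_{gs} = \text{scale}_{\text{series}(s)} \cdot (b_g + \mu_{g,\text{class}(s)} + \varepsilon) + \text{offset}_{\text{series}(s)}$
with $\varepsilon \sim N(0, \sigma^2)$ — Gaussian noise on the log2
scale (the modelling assumption of the moderated t-test) and affine
per-series batch effects, chosen precisely because joint quantile
normalization must be able to remove them. Samples are assigned to
series round-robin within class so every series sees every class.

The default desk-scale design (`defaultDesign`) fixes the study
conditions: 5 classes with sizes 26/80/60/53/29, 2000 genes, 50
planted genes with effect step $\Delta = 3.0$ log2 units, noise sd 0.5,
and two series with offsets 0/+2 and scales 1/1.1. Two generator
choices deserve explanation:

* **Class-exchangeable planting.** Each planted gene draws a fixed
  level multiset (coverage 6–10 at threshold 2.5, weighted toward the
  low-coverage patterns that dominate real multiclass DEG panels),
  centers it, scales by $\Delta$ and assigns levels to classes by
  random permutation. With level steps at multiples of $\Delta = 3$
  and threshold 2.5, any two distinct levels are separated, so the
  attainable coverage values are $\{6,\dots,10\}$ — coverage exactly 5
  is not representable by any level pattern, and "planted coverage at
  least 5" is realised as 6–10. The permutation makes every class's
  marginal distribution of planted values identical, which matters:
  quantile normalization *assumes* comparable distributions across
  samples, and class-asymmetric planting would make it erode the
  planted fold changes by construction rather than by any defect of
  the method.
* **Per-gene baselines.** Null genes draw baselines
  $b_g \sim N(8, 2^2)$ (in the default design; `simulationDesign`
  defaults to a common baseline). Real log2 expression spans many
  units across genes; a single common baseline would leave the pooled
  distribution nearly empty where planted values fall, and quantile
  normalization is only as accurate as the density of the reference
  distribution at the mapped ranks.

What the simulator does **not** emulate: probe-level effects,
count-based RNA-seq noise (mean–variance dependence), missing values,
correlated gene modules, or overlapping pathologies with genuinely
graded expression. Perfect classification on the synthetic fixture
therefore shows the chain is correct and leak-free, not that real
five-class discrimination is easy; real studies sit well below the
synthetic ceiling.

# Problem sizes and runtime

The shipped validation runs use the desk-scale design above
(2000 × 248, one full pipeline pass cached and shared across tests), a
5000-gene variance-prior recovery simulation, 8-gene mRMR oracle
fixtures, and a 200 × 150 noise canary. The complete test suite runs in
about half a minute; `scripts/acceptance.R` in about the same.

# Known limitations

* Coverage is a count, not a graded effect size: a gene covering 6
  pairs at huge margins ties with one covering 6 pairs marginally;
  the mean |t| tiebreak is a heuristic.
* The raw p-value gate performs no multiple-testing control by
  default (by design; `adjust = "BH"` exists).
* The KS outlier fence is adaptive and will flag ~the boxplot-rule
  share of borderline samples even in clean series.
* Quantile normalization assumes most genes are non-differential and
  sample distributions comparable; with extreme, class-concentrated
  signal it attenuates fold changes near the distribution tails.
* mRMR's plug-in mutual information is biased upward for small sample
  counts; with the study's ~250 samples and 3-state variables the bias
  is immaterial for ranking, but rankings of very small studies should
  be read cautiously.
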