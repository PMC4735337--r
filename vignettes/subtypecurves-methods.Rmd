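---
title: "Methods: learning curves for RNA-seq subtype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning curves for RNA-seq subtype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`subtypecurves` estimates how the accuracy of breast-cancer molecular
subtype and receptor-status prediction depends on training-set size and
sequencing depth. This vignette is the package's own account of the models
and procedures it implements, the parameters that matter, and the design
choices made where the design was genuinely open.

## The synthetic cohort generator

Real cohorts of this kind are controlled-access, so every stage of the
pipeline is exercised against a generator that reproduces the statistical
structure the analysis assumes, not any particular dataset.

A cohort is drawn as follows. Subtype labels are allocated by deterministic
largest-remainder apportionment of the class proportions — the default is
the 132/65/393/190/105 Basal/Her2/LumA/LumB/Normal split of an N = 885
reference cohort — and then shuffled; the deterministic allocation (rather
than a multinomial draw) means exact class counts are reproducible and
stratification tests are not at the mercy of sampling fluctuation. Each of
the `n_genes` features (default 20477, of which three are the literal marker
genes ESR1, PGR, ERBB2) receives a baseline log2 mean drawn once per cohort
from N(4, 2²). A random subset of `n_informative` genes (default 600, a
minority of the transcriptome, as in real subtype signatures) is eligible
for class effects: per class, each informative gene gets a shift of
−`effect_size`, 0 or +`effect_size` with equal probability. LumB copies
LumA's shift for a `lumAB_correlation` fraction of informative genes
(default 0.95), which is what makes the two luminal subtypes molecularly
similar and produces the characteristic LumA ↔ LumB confusion.

Receptor biology is wired to subtype: ER truth is positive exactly for the
luminal classes, Her2 truth for the Her2-enriched class, and PR truth is
Bernoulli conditional on ER (defaults P(PR+|ER+) = 0.85, P(PR+|ER−) = 0.10,
chosen as clinically typical values). In truly positive samples the
corresponding marker gene's latent mean is raised by `marker_shift` (default
2 log2 units) *before* counts are drawn, so marker expression carries the
biology; the observed clinical labels are the truth flipped independently
with probability `receptor_noise_rate` (default 0.03), emulating assay and
records noise.

Counts are negative-binomial (gamma-Poisson) with a single global
dispersion, mean proportional to `2^latent` rescaled to a log-normal
per-sample library size (default mean 5×10⁶ — the depth at which subtype
classification is expected to saturate — CV 0.3). Identical configurations
and seeds give bit-identical cohorts.

**Calibration.** Nothing pins the generator's effect-size distribution to a
real cohort, so `effect_size` and `dispersion` were calibrated once, before
any acceptance checking, to reproduce the qualitative learning-curve shape
expected of this problem: accuracy in the mid-0.8s at N = 100 rising to a
plateau that begins near N ≈ 350, with LumA ↔ LumB as the dominant
confusion. The frozen defaults are `effect_size = 0.45`,
`dispersion = 0.30`, `lumAB_correlation = 0.95`.

**What the generator does not emulate:** batch effects, isoform structure,
gene–gene correlation beyond the shared class shifts, read-level artifacts
(adapter content, mapping ambiguity), and tumor purity. Tests passing on
synthetic cohorts therefore demonstrate that the *pipeline machinery* is
correct and well calibrated, not that real-data accuracies will match;
absolute numbers on real cohorts will differ.

## Preprocessing

Normalization is median-of-ratios: gene *i*'s reference is its geometric
mean across samples, and sample *j*'s size factor is the median of
`counts[i, j] / geomean_i` over genes with an all-positive row. Expression
is `log2(count/sf + 1)`; the log2 pseudo-count transform is the package's
choice (standard, and it keeps centroids interpretable in log2 units). The
top-variance filter computes variances on normalized log2 expression — a
deliberate decision, recorded here because computing them on raw counts is
also defensible — and retains `ceiling(fraction × n_genes)` genes, ties
broken by input order; at 25% a 20477-gene matrix keeps exactly 5120 genes
(the ceiling convention is what makes 20477 × 0.25 = 5119.25 → 5120).

Read-depth experiments use binomial thinning: each gene count in a sample
with total T above the target is replaced by a Binomial(count, target/T)
draw, which is expectation-equivalent to subsampling reads before counting —
the right primitive when the artifact starts from count matrices rather than
FASTQs. Thinned matrices are renormalized (size factors recomputed) before
analysis. Outlier flagging automates PCA-based inspection: a sample is
flagged when its Hotelling score distance on the leading components or its
residual sum of squares exceeds a stated empirical quantile; explicit
quantiles replace visual judgment because inspection is not reproducible.

## Classifiers and tuning

Nearest shrunken centroids is implemented from the published construction
(standardized class-vs-overall contrasts, soft-thresholding, reconstruction,
minimum standardized distance minus twice the log prior). The offset `s0` is
the median of the pooled within-class SDs — the published convention,
recorded explicitly. Class priors are empirical training proportions. The
elastic net is glmnet's multinomial loss (chosen over one-vs-rest; the
multinomial coupling matches how the model is normally used for this
problem), and random forests are ranger with a fixed seed and one thread so
results are exactly reproducible.

Tuning is stratified inner cross-validation (default 5 folds; 5 is the
standard desk-scale choice) over a grid: elastic-net α over 0.1…1.0 with a
20-value λ path computed from the tuning data at the largest α in the grid;
forest `num_trees = 500` with variables-per-split √p and p/4; NSC threshold
over a 15-point path from 0 to the largest absolute contrast (beyond which
all centroids have collapsed). Data-dependent grid entries are resolved on
the tuning data only. Ties select the first grid point, so tuning is
deterministic.

## The learning-curve engine

"Cross-validation" here means independent repetitions of a stratified
10%-holdout: each round draws a fresh class-balanced outer test set
(largest-remainder apportionment of `round(0.1 × N)`, half-up — the only
rounding consistent with a test set of 89 with per-class counts
13/7/39/19/11 at the reference class sizes), subsamples the remainder to the
requested training size (again stratified), tunes, refits, and scores the
untouched outer test. Redrawing the holdout each round (rather than fixing
folds) is the package's reading of a repeated-cycle protocol; it makes
rounds exchangeable and the SEM across rounds meaningful. A master seed
spawns per-round and per-depth seeds deterministically, so the full
factorial over rounds × sizes × classifiers × datasets × read depths is
reproducible bit for bit. Per-class accuracy is class-wise recall (the
diagonal of the row-normalized confusion matrix) and balanced accuracy is
its unweighted mean over classes present; with a single round the SEM is
reported as 0 with a warning.

## Receptor-status curves

Each receptor model is a logistic regression of the clinical status on one
marker gene's expression. ROC cutpoints are the midpoints between adjacent
distinct sorted scores plus ±∞ sentinels — exhaustive and deterministic —
and the operating point maximizes Youden's J = sensitivity + specificity − 1,
ties resolved toward higher specificity and then the larger cutpoint. The
cutoff is chosen on training scores only and applied unchanged to the test
set; binary accuracy is the headline metric with sensitivity/specificity
and training AUC emitted alongside.

## The unsupervised arm

Training samples are clustered by average-linkage (UPGMA) on
1 − Pearson-correlation dissimilarity. Clustering operates on gene-centered
expression: with raw log2 values the per-gene baseline (SD ≈ 2 under the
generator, similar on real data) dominates every inter-sample correlation
and the dendrogram reflects noise; centering is the standard preparation in
correlation-based expression clustering. The tree is pruned top-down: at
each node a significance-of-clustering test compares the cluster index
CI = WSS/TSS of the node's best 2-means split against draws from a
single-Gaussian null. The null covariance is diagonal with the sample
spectrum soft-thresholded — eigenvalues shifted down by a threshold chosen
to preserve total variance and floored at a background variance estimated
from the MAD of all centered entries. Both choices matter numerically: using
the dendrogram's own (often unbalanced) split as the observed statistic, or
flooring the spectrum without the variance-preserving shift, each makes the
test so conservative that genuine five-cluster structure survives as a
single cluster. The Monte-Carlo p-value uses the add-one convention
(k+1)/(n_sim+1), so the smallest attainable value is 1/(n_sim+1); defaults
are α = 0.05 and 100 simulations per node. Splits leaving fewer than two
samples on a side are not tested and terminate.

Cluster centroids are labeled by Spearman correlation against reference
subtype centroids, processed in the fixed priority order Basal, Normal,
Her2, LumA, LumB; each label takes the best still-unassigned cluster (ties
to the lowest cluster index), and with more clusters than labels the surplus
clusters take their own best reference (duplicates allowed) — with fewer
clusters than labels, the highest-priority labels win, which is the
documented fallback when pruning returns fewer than five clusters. Both
centroid sets are gene-centered (by the reference means) before correlating,
for the same baseline-domination reason as above. On synthetic cohorts the
reference centroids are the cohort's true latent class means; on real data
this is the substitution point for externally published subtype centroids.
Test samples are classified against the labeled cluster centroids with the
threshold-0 NSC rule (plain nearest centroid on standardized distance);
rounds that prune to a single cluster predict that cluster's label
throughout and are recorded with a warning.

## Numerical and degenerate-input conventions

Largest-remainder apportionment breaks remainder ties by category order;
variance-filter ties break by input order; NSC prediction ties break by
fixed class order; tuning ties break by grid order; Youden ties prefer
specificity, then the larger cutpoint. A training set containing a single
class degenerates to constant prediction. `alpha = 0` in pruning always
yields one cluster. Constant sample profiles make correlation undefined and
are rejected by name. Size factors are undefined (and error) when no gene
has an all-positive row.

## Problem sizes used in tests and the acceptance script

The package's own checks run at desk scale, chosen so the whole suite
exercises every pathway on cohorts large enough to show the phenomena:
unit-test cohorts of 150–300 samples × 300–400 genes; learning-curve
properties on the full 885 × 20477 default cohort with a 50-gene curated
panel, 10–20 rounds and sizes 100–350; cluster recovery on a 500-sample
well-separated cohort; SigClust null calibration with 200 replicates of a
50 × 10 Gaussian at 99 simulations each; thinning expectations over 200–1000
seeded draws. The `informative_panel()` helper builds the curated-panel
analogue by taking each subtype's most-deviating informative genes in
round-robin order — mirroring how minimal centroid panels are assembled, and
guaranteeing every class (including LumB) contributes discriminative genes.

## Known limitations

Accuracies on synthetic cohorts are calibrated to shape, not to any real
cohort's absolute values. The single global NB dispersion understates the
gene-specific mean–dispersion trend of real RNA-seq. The SigClust null is
the simplified diagonal form; a factored-covariance estimate could be
substituted where more fidelity is needed. The unsupervised arm's label
transfer depends on reference centroids, which real deployments must supply
from published sources. Raw-read processing (trimming, alignment, counting)
is out of scope: the pipeline starts at count matrices.
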