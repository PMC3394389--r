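---
title: "Methods: eigenvalue-based detection of outlier genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eigenvalue-based detection of outlier genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigfusion)
```

## The problem

Structural rearrangements — gene fusions, amplifications, deletions — change
a transcript's abundance in a *subset* of cancer samples. Two failure modes
dominate naive screens of expression matrices for such genes:

* statistics that contrast all cancer samples against all normals (t-test,
  SAM) dilute a signal present in, say, 5% of tumors to invisibility;
* statistics that look for heavy per-gene tails (COPA and its descendants)
  cannot tell a gene overexpressed in *a few* cancer samples from a gene
  overexpressed in *all* of them — an ordinary biomarker, which for this
  task is a false positive.

The statistic implemented here addresses both at once, and is symmetric in
direction: genes *under*-expressed in a subset (candidate deletions) score
identically to genes over-expressed by the same amounts.

## Transformation

For gene $i$ with expression $x_{ij}$ over samples $j$, cancer group $S1$
and normal group $S2$:

$$\hat x_{ij} = \frac{x_{ij} - \mathrm{AVGmedian}^{S1}_i}{\mathrm{MAD}_i},
\qquad
\mathrm{MAD}_i = \mathrm{median}_j\, |x_{ij} - \mathrm{median}(x_{i\cdot})|.$$

$\mathrm{AVGmedian}^{S1}_i$ is the mean of three medians of the cancer
values: their median $m$, the median of the values strictly above $m$, and
the median of the values strictly below $m$. An empty strict subgroup
contributes $m$ itself, which keeps the construction defined for degenerate
genes and reduces it to the plain median. Even-length medians use the
midpoint convention throughout.

Centering on the cancer-group median structure is the biomarker filter: a
gene elevated in essentially all cancer samples is centered at its elevated
level, so the cancer samples retain no excess deviation, while the normal
samples acquire large *negative* deviations that drive the group contrast
(below) negative. The three-median average rather than the plain $S1$ median
keeps the center stable when a rearrangement is frequent (up to about half
of the cancer group).

The MAD is the raw median absolute deviation — deliberately without the
1.4826 normal-consistency factor, since only the relative scale matters. A
gene with $\mathrm{MAD}_i = 0$ (more than half its values identical) is
undefined under the map; such genes are *dropped* and reported, not
zero-filled, so they cannot distort the denominator below. The transform is
invariant under positive affine changes $x \mapsto a x + b$ of a gene's raw
values, and odd under negation ($\hat{(-x)} = -\hat x$), which is what makes
deletion and amplification detection exactly symmetric.

## Score

$$\mathrm{Score}_i
 = \frac{E(\hat x_i)\,\bigl(E(\hat x_i^{S1})/|S1| - E(\hat x_i^{S2})/|S2|\bigr)}
        {E(\hat X_{-i})}$$

where $E(v)$ of a vector is the largest eigenvalue of $v v^\top$, i.e. its
sum of squares, and $E(\hat X_{-i})$ is the largest eigenvalue of
$\hat X_{-i} \hat X_{-i}^\top$ — the transformed matrix with row $i$
deleted. Genes are ranked by descending score; ties keep input order.

Three ingredients, in words:

* $E(\hat x_i)$ rewards total squared deviation, which a few large spikes
  dominate;
* the group contrast is positive only when the squared deviations
  concentrate in the cancer group *per sample*; biomarkers come out strongly
  negative because their normal samples carry the deviations after
  centering;
* the leave-one-out denominator measures the spectral energy of the rest of
  the matrix, making the score a *relative* quantity: a gene is interesting
  only if its energy is large against the strongest pattern in the remaining
  data.

**Group-energy normalization.** The raw difference
$E(\hat x_i^{S1}) - E(\hat x_i^{S2})$ of summed squares confounds the group
contrast with the group sizes: with $|S1| = 20$ vs $|S2| = 180$ the second
term dominates every gene and sparse spike-ins sink to the bottom of the
ranking. Dividing each group energy by its size removes the confound, leaves
the ranking unchanged when $|S1| = |S2|$, and is what makes the statistic
robust across cancer-group proportions — the property the method is built
around. The package therefore defaults to per-sample mean energies
(`group_energy = "mean"`); the literal summed form remains available as
`group_energy = "sum"` for comparison.

**Leave-one-out computation.** $E(\hat X_{-i})$ for every $i$ naively costs
one decomposition per gene. Since row deletion is a rank-one downdate of the
$n \times n$ sample-space Gram matrix $G = \hat X^\top \hat X$, the package
eigendecomposes $G$ once and solves, per gene, the secular equation of
$G - x_i x_i^\top$ by bisection on $[\lambda_2, \lambda_1]$, where the
secular function is strictly monotone. This is $O(n^2)$ per gene, exact to
floating-point precision (80 bisection steps), and is verified in the test
suite against explicit row-deletion singular value decompositions at
relative $10^{-8}$.

## Outlier samples, direction, permutation p-values

* **Outlier samples** of a gene are the cancer samples whose transformed
  value falls outside the Tukey fence
  $[q_{25} - f\,\mathrm{IQR},\; q_{75} + f\,\mathrm{IQR}]$ of the gene's
  whole transformed profile, with $f$ = `fence_multiplier` (default 1.0, the
  fence the OS-family statistics use). Quantiles are linearly interpolated
  between order statistics (`stats::quantile` type 7) everywhere in the
  package.
* **Direction** is `over` if all fence-exceeding cancer values are positive,
  `under` if all are negative, `mixed` otherwise (including the vacuous case
  of no fence-exceeding values, where no direction is supported by any
  outlying sample).
* **Permutation p-values** reshuffle the sample labels (preserving $|S1|$),
  recompute all scores, and pool the permuted scores of *all* genes into one
  null distribution; $p_g = (1 + \#\{\text{null} \ge s_g\})/(1 + GP)$. The
  pooling is what lets 100 permutations resolve p-values near $10^{-3}$ and
  below: per-gene nulls of size 100 cannot. It assumes gene scores are
  exchangeable under the null, which holds for the i.i.d. benchmark and is
  an approximation on real data where a handful of extreme genes can fatten
  the pooled tail and make all p-values conservative.

## Comparator statistics

All comparators share the type-7 quantile convention and stable descending
ranks, and all operate on robustly standardized values so that each is
location/positive-scale invariant:

* **COPA** — the `copa_percentile`-th percentile (default 80) of the
  overall-median/MAD-standardized cancer values.
* **OS** — the sum of standardized cancer values strictly above
  $q_{75} + \mathrm{IQR}$ of the standardized whole profile.
* **ORT** — centers at the normal-group median, scales by the pooled median
  absolute deviation about the two group medians, fences on the scaled
  normal values.
* **GTI** — on the standardized profile, outlier proportion of the cancer
  group times the mean exceedance of its outliers over $q_{75}(S1)$, divided
  by the robust scale $\max(|\mathrm{median}|, \mathrm{MAD})$ of the
  standardized profile (which standardization pins at 1). The exact
  published constant of GTI varies between descriptions; the formula is
  isolated in one function so a different variant is a one-line change.
* **KS** — the two-sample Kolmogorov–Smirnov statistic via
  `stats::ks.test`, included as the representative classical two-group
  statistic.

## The synthetic benchmark

`simulate_dataset()` emulates a spike-in design: a `n_genes x n_samples`
(default 1000 × 200) i.i.d. Gaussian background $N(\mu, \sigma^2)$ plus
additive $N(0, \texttt{noise\_sd}^2)$ noise, the first `cancer_size` samples
labeled cancer, and one appended test gene per spike count $k$, formed by
adding (or, for deletions, subtracting) the constant $u$ — the maximum value
of the background before embedding — to its first $k$ cancer samples. The
noise standard deviation defaults to 1 ($\sigma$'s own scale); since every
statistic here is scale invariant, the noise level only matters through its
ratio to $\sigma$, and the benchmark's difficulty is in fact invariant to
the overall scale. The default spike counts are
$k \in \{2, 5, 10, 20, 50, 80, 100, 120, 150\}$, filtered to
$k \le$ `cancer_size` per scenario; `scenario_sweep()` varies
`cancer_size` over $\{20, 50, 100, 120, 150, 180\}$ with per-scenario seeds
derived from the base seed.

Truth labels: a test gene is a **positive** when $k$ is below half the
cancer-group size, a **biomarker** (negative control) when $k$ equals it;
intermediate $k$ — frequent but not universal alterations — are labeled
**ambiguous** and excluded from confusion counting, since they are neither
clean subset outliers nor clean biomarkers. Affected samples are the first
$k$ cancer samples by default for reproducibility (`random_affected = TRUE`
draws them at random).

What the generator does *not* emulate: gene–gene correlation, batch
effects, heavy-tailed or count-distributed expression, and probe-level
artifacts. Passing the benchmark therefore shows that the statistic ranks
subset spikes above i.i.d. noise and below-biomarker, not that it is robust
to correlated structure in real cohorts — on real data the leave-one-out
denominator absorbs the dominant global pattern, but correlated blocks of
genes can still share energy.

## Evaluation conventions

With a top list of size `top_n` (default 10): FP = biomarker test genes in
the top list, TP/FN = positive test genes inside/outside it, TN = biomarker
genes outside. Counting is over labeled test genes only; background genes
entering the top list are reported separately as `background_intrusions`.
The reported `fpr` and `fnr` are the discovery proportions FP/(FP+TP) and
FN/(FN+TN) (not ROC rates), defined as 0 when their denominator is 0 — no
discoveries means no false discoveries. The f-measure is the harmonic mean
of precision and recall with the 0/0 → 0 convention. For the ROC/AUC,
positives are the positive test genes and negatives are the background genes
plus the biomarker test genes (a full negative set is required for
sensitivity/specificity; biomarkers belong in it because ranking them high
is precisely the failure mode under study); the AUC is the tie-aware
pairwise probability, computed from rank sums.

A deliberate consequence of the single `top_n` cut: a positive test gene
ranked 40th of 1010 counts as a false negative even though it is nowhere
near the bottom of the list. This makes TP/FN a partition and the f-measure
a strict criterion; with the default benchmark the smallest spike counts
($k = 2$, a 1% outlier fraction) hover around the top-10 boundary at large
cancer-group sizes, so the minimum f-measure across a sweep is a stochastic
quantity — the acceptance script reports exactly what it computes.

## Clinical association

`rearrangement_vector()` binarizes a gene over the *cancer* samples (1 =
beyond the Tukey fence), since clinical outcomes attach to tumors;
`hamming_association()` reports both the normalized Hamming distance to a
binary clinical vector and the conditional rate
$P(\text{clinical} = 1 \mid \text{rearranged} = 1)$. Both are returned
because a small distance is often *interpreted* as a high conditional rate,
yet the two coincide only when the vectors' supports align; reporting both
surfaces the ambiguity instead of hiding it.

## Numerical choices and degenerate inputs

* Medians: midpoint convention for even counts; strict inequalities define
  the upper/lower subgroups, empty subgroups fall back to the group median.
* Quantiles: type 7 (linear interpolation) everywhere.
* Ranks: stable descending; ties keep input gene order.
* Zero-MAD genes: dropped with a reason, never zero-filled; an all-degenerate
  matrix is an error, as is scoring a single retained gene (the leave-one-out
  denominator is undefined).
* Secular bisection: 80 iterations on $[\lambda_2, \lambda_1]$; a gene
  numerically orthogonal to the top eigenvector keeps $\lambda_1$.
* Permutation p-values use the add-one estimator, bounded below by
  $1/(1+GP)$.

## Problem sizes used by the tests and acceptance script

The test suite exercises the full benchmark geometry (1000 × 200) for the
sweep, sensitivity and null-uniformity checks (3 sweep seeds; 20 replicate
seeds at cancer size 100; 50 permutations × 1000 genes for the uniformity
check) and small matrices (≤ 40 × 16) for oracle comparisons — sizes chosen
so the whole suite completes in a few minutes while keeping every check at
the benchmark's stated scale.

## Known limitations

* The group contrast is a difference of mean energies, not a variance-
  stabilized statistic; very small normal groups make it noisy.
* The pooled permutation null assumes exchangeability of gene scores.
* The Tukey-fence outlier-sample calls include occasional chance background
  samples (about one per gene at the default fence); `fence_multiplier`
  trades sensitivity against such intrusions.
* Expression values are used as supplied; whether to log-transform a cohort
  first is left to the user, and the choice changes what "outlier" means.
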