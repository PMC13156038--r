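---
title: "Methods: regional receptor mapping, spatial nulls, and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional receptor mapping, spatial nulls, and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropepmap)
```

## The problem

Regional maps of gene expression, receptor density and functional
specialization live on a common parcellation of the brain. Questions
about such maps — does a neuropeptide receptor's expression colocalize
with neurotransmitter receptor densities? does a receptor set share a
latent axis with cognitive term maps? — are questions about spatially
autocorrelated data: neighbouring regions resemble each other, so naive
permutation tests wildly overstate significance. This package provides
the full chain needed to ask these questions honestly: data containers
and readers, expression preprocessing, two spatial null models,
dominance-based colocalization, partial least squares correlation
(PLSC), PCA profiling, and evolutionary summary statistics, together
with a synthetic-data module that plants known truth so every stage can
be validated quantitatively.

## Data model

A `region_atlas` indexes regions (integer `region_id`, structure class
`cortex`/`subcortex`/`hypothalamus`, a free-text stratum, hemisphere,
3-D centroid in millimetres). A `regional_matrix` couples a
regions-by-variables matrix to its atlas; row order is always atlas
order, and all on-disk tables are tab-delimited with `region_id` as the
join key, so misalignment cannot happen silently. Missing values are
explicit (`NA`); operations reject them unless they document otherwise
(only donor aggregation does). Inter-region distance is the Euclidean
distance between centroids: the analyses here need a distance that is
defined uniformly for cortex, subcortex and hypothalamus, which a
surface-based geodesic is not.

## Preprocessing

Quality control keeps genes whose mean probe intensity, correlation
with RNA-seq and differential stability pass thresholds (defaults 0.2 /
0.2 / 0.1). Comparisons are inclusive by default because annotation
tables are printed at two decimals: a printed 0.20 under a strict
"greater than 0.2" rule reflects an underlying value that passed before
rounding. Differential stability is defined as the mean over donor
pairs of the Pearson correlation of a gene's regional profile — the
field-standard construction; Pearson (not Spearman) is used as the
donor matrices are already normalized to a common scale. The robust
sigmoid normalization uses `IQR/1.35` as its scale, consistent with the
standard deviation under normality; a zero-IQR slice is an error by
default (a constant-0.5 policy is available) because a constant slice
usually signals an upstream join problem rather than real data.
Probe-level filtering operates upstream of region-level data; it is
included as a documented contract (`filter_probes()`,
`select_probes()`) with both readings of the ambiguous
below-background exclusion rule available behind a flag, the default
being the reading that keeps reliably detected probes.

## Spatial null models

**Variogram-matched surrogates.** A surrogate map must preserve two
things: the value distribution of the target and its spatial
autocorrelation as summarized by the empirical variogram
$\gamma(h) = \tfrac12\,\mathrm{E}[(x_i - x_j)^2 \mid d_{ij} \approx h]$.
Each surrogate is built by (1) randomly permuting the target values,
(2) smoothing the permutation with a Gaussian kernel at each of several
candidate scales and mixing with white noise, $z = \sqrt{a}\,S_\sigma
\pi(x) + \sqrt{b}\,\varepsilon$, where $(a, b)$ solve a least-squares
match between the candidate's variogram and the target's under the
constraint $a\,\mathrm{var}(S_\sigma \pi(x)) + b = \mathrm{var}(x)$,
and (3) re-ranking $z$ onto the sorted target values, which makes the
surrogate an exact permutation of the target. The variance constraint
matters: adding independent noise raises the semivariance by a
constant, and pinning total variance keeps the final re-ranking — a
monotone, variance-restoring transform — from inflating the matched
variogram. The candidate scale is chosen by the variogram error of the
finished (re-ranked) candidate, with one shared noise draw across
scales so the choice compares scales rather than noise realizations.

Defaults: 25 lags up to the 25th percentile of pairwise distances
(long-lag pairs are sparse and noisy), Gaussian lag-kernel bandwidth of
three lag spacings (wide enough that single-realization variogram
estimates are smooth enough to fit), and eight candidate smoothing
scales geometrically spaced from the smallest positive distance to a
third of the atlas diameter. On a 455-region atlas with a target
correlation range of a quarter of the atlas diameter, surrogates
reproduce the target variogram to a mean relative L2 error below 0.15
(the test suite checks 100 surrogates), and their Moran's I closely
tracks the target's.

**Matched-gene nulls.** The second null replaces a target gene by real
(here: simulated) genes matched on two criteria: spatial
autocorrelation, measured by Moran's I, and value distribution,
measured by the two-sample Kolmogorov–Smirnov statistic. Per draw, 100
candidates are sampled from the pool (excluding the target and any
listed genes); candidates are ranked on |ΔMoran's I| and on KS
(both ascending) and the best mean rank wins, ties broken by smaller
|ΔMoran's I|, then alphabetically — a fully deterministic rule given
the candidate set. Moran's I uses row-normalized k-nearest-neighbour
weights (k = 10 by default). The weight scheme is a genuine modelling
choice the matching inherits, so it is an explicit argument rather than
a constant.

**Empirical p-values** use the add-one estimator
$p = (k + 1)/(m + 1)$, so $p = 0$ is impossible and $m = 10{,}000$
nulls bound p below by $1/10{,}001 \approx 0.0001$. Two-sided extremity
is measured as absolute deviation from the null mean by default; a
doubled-tail variant is available. Calibration is verified in the test
suite: for independent smooth map pairs, both surrogate-based and
matched-gene-based p-values are uniform on (0, 1] (Kolmogorov–Smirnov
against the uniform, 200 replicates of 200 nulls each). One practical
finding from that study is encoded in the test setup: matched-gene
nulls need a pool large enough (thousands of genes) that the selected
nulls are not dominated by repeats, otherwise the null distribution is
too narrow and p-values become anticonservative.

## Dominance analysis

Colocalization of one receptor map with a set of p predictor maps is
quantified by decomposing the OLS R² over predictors: predictor k's
*total dominance* is the average over subset sizes of its mean R²
increment when added to subsets lacking it — the Shapley value of R²,
so total dominances are model-complete and sum exactly to the full R².
All $2^p - 1$ subset R² values are computed by sweeping a single
cross-product matrix of `[X y]`, which makes 38 targets × 65,535
subsets (p = 16) a desk-scale computation; an explicit bound
(`max_predictors = 20`) guards the exponential cost. Adjusted R² uses
the standard `(n − 1)/(n − p − 1)` correction. The
ionotropic-versus-metabotropic contrast averages each target's relative
contributions within the two receptor classes and compares the
resulting per-target vectors with an unpaired pooled-variance t-test —
with k targets this has 2k − 2 degrees of freedom (74 for 38 targets);
a paired variant is available behind a flag.

## PLSC and PCA

Both blocks are column-standardized; the SVD of the cross-covariance
$X^\top Y$ yields paired latent variables. Covariance explained per
latent variable is the squared-singular-value share (the σ²-share, not
the σ-share). Loadings are Pearson correlations of each original column
with its side's score. Signs follow a deterministic convention — per
latent variable, the weight side with the larger ℓ∞ entry is made
positive, both sides flipped together — so results are reproducible
across BLAS implementations.

Permutation inference rebuilds Y under either null: per-column
variogram surrogates, or one matched null gene per column per
permutation (columns matched independently). Null singular values are,
by default, the sorted singular values of the permuted
cross-covariance, compared rank for rank with the empirical ones. An
alignment variant (`align = TRUE`) instead projects the permuted
cross-covariance onto the empirical y-weights
($\tilde\sigma_k = \lVert C_{\mathrm{perm}} v_k \rVert$, which recovers
$\sigma_k$ exactly for the unpermuted matrix). Alignment keeps each
latent variable's null on its own direction, but it is anticonservative
for the first latent variable under the global null — the empirical
$\sigma_1$ is maximized over directions while the projected null
statistic is not — and the package's calibration study confirms the
effect is large. Since calibrated inference is the design goal, the
like-with-like sorted comparison is the default and alignment is the
option. Each latent variable's p-value is reported without a
model-selection rule; "how many latent variables are significant" is
left to the analyst.

Bootstrap confidence intervals resample regions with replacement and
use percentile intervals — the simplest defensible choice when no
particular interval construction is mandated; bootstrap latent
variables are sign-aligned to the empirical ones by weight-vector dot
products. Cross-validation re-learns standardization parameters on
training rows only (no leakage), fits on `floor(0.7 n)` regions and
correlates projected test scores. PCA of nuclear expression profiles is
column-centered (not scaled — the inputs are already normalized to
[0, 1]) via SVD.

## Synthetic data: what it emulates and what it does not

All generators are pure functions of their parameters and a seed.
Regional maps are zero-mean Gaussian random fields with exponential
covariance $\mathrm{sill}\,[(1-\mathrm{nugget})\,e^{-d/\rho} +
\mathrm{nugget}\,\mathbf{1}_{d=0}]$ — one interpretable range parameter
ρ, with a 1e-10 diagonal jitter before Cholesky factorization.
Synthetic atlases place cortical centroids on a 60–80 mm shell and
subcortical ones in a core below 30 mm so cortex–subcortex contrasts
are geometrically meaningful. Gene pools draw per-column ranges
uniformly between stated bounds and record the truth. Planted-latent
designs share a single smooth latent score (range = atlas diameter / 4,
so spatial nulls face a realistic challenge) scaled so the planted
dimension carries a stated share of the squared-singular-value mass of
the expected cross-covariance. Dominance designs orthonormalize raw
smooth fields before mixing, so each predictor's population R² share
equals its planted contribution; by default residual noise is scaled so
the full-model population R² equals the contributions' sum. Donor
stacks mix a shared smooth signal (weight √reliability) with donor
noise, both standardized to unit sample variance per gene — a smooth
signal's sample variance across regions sits below its marginal
variance, and without standardization the realized inter-donor
correlation attenuates below the planted reliability — so differential
stability recovers the reliability without bias.

The generators emulate the *statistical* structure the analyses assume
— spatial autocorrelation with heterogeneous ranges, shared latent
axes, known predictor contributions, known donor reliability. They do
not emulate microarray probe-level noise, background intensity, donor
demographics, hemispheric asymmetries, or the heavy-tailed and bounded
value distributions of real expression data. Passing tests therefore
demonstrate that the estimators and null models are correct and
calibrated under their stated assumptions, not that any particular
biological conclusion is robust to violations of those assumptions.

## Numerical choices and degenerate inputs

Constant maps are errors for variograms, Moran's I and PLSC
(zero-variance columns are named). Rank ties in re-ranking are broken
by first occurrence, making surrogate generation deterministic given
the seed. Zero-IQR normalization slices and all-skipped donor pairs
follow explicit, documented policies. Bootstrap resamples with a
zero-variance column are redrawn and counted. The dominance sweep
refuses rank-deficient designs rather than silently pseudo-inverting.
Kendall's W is computed as χ²/(n(k−1)) from the Friedman statistic
with mid-rank ties and no tie-correction term by default (a corrected
variant is behind a flag), matching the convention of the common
implementations that report both numbers together.

## Problem sizes used in the test suite

The suite validates parameter recovery at the scales the analyses are
meant for: PLSC weight recovery on a 455-region atlas with 125 + 38
variables, dominance-share recovery at 2,000 regions, and the full
65,535-submodel sweep at p = 16. Calibration studies use 200 replicates
of 200 nulls on ~110-region atlases and a 2,000-gene pool — sizes
chosen so the whole suite completes in minutes on a single CPU while
keeping Monte-Carlo error well below the tolerances being checked.

## Known limitations

Euclidean centroid distances ignore cortical folding; surrogate quality
is assessed against the variogram only (higher-order spatial structure
is not matched); matched-gene nulls assume the pool spans the target's
autocorrelation range — a target outside the pool's range cannot be
matched, only approximated; dominance analysis is OLS-based and limited
to ~20 predictors by design; PLSC assumes linear relations between
blocks. The evolutionary statistics summarize upstream outputs (aligned
sequences, per-branch rate tables) and deliberately do not implement
alignment or selection models.
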