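---
title: "Plasticity phenotyping of visual-cortex synaptic proteins: methods and design"
author: "plastphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasticity phenotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastphen)
```

## The scientific problem

Monocular deprivation (MD) during the critical period reorganizes the
visual cortex (V1), and different treatments — reverse occlusion (RO),
binocular deprivation (BD), or simply restoring binocular vision (BV) —
leave behind different molecular states, only some of which support
recovery of acuity. Those states can be read out from Western-blot
measurements of seven synaptic proteins: the AMPA receptor subunit GluA2,
the NMDA receptor subunits GluN1, GluN2A and GluN2B, the GABA-A receptor
subunits alpha1 and alpha3, and the presynaptic marker synapsin. Because
univariate comparisons of seven proteins across six rearing conditions
and three V1 regions are hard to interpret, the package implements a
data-driven phenotyping workflow:

1. normalize band densities (per-gel control, then the 5 wk normal
   reference);
2. per-condition protein correlation networks with Bonferroni-corrected
   significance and dendrogram seriation;
3. centered-SVD PCA with variance and cos^2 diagnostics;
4. construction and screening of nine *plasticity features*;
5. tSNE + k-means clustering of samples, with condition "subclusters";
6. color-coded plasticity phenotype bands with a bootstrap Monte-Carlo
   comparison against the 5 wk normal reference;
7. a population decay-kinetics model for NMDAR and GABA-A receptor
   subunit mixes.

Every stage is exercised end to end on a synthetic-data generator that
emulates the study design, so the pipeline is fully testable even though
the original tissue data are not publicly deposited.

## Normalization and matrix assembly

Raw band densities are divided by the control-sample band run on the same
gel (`normalize_to_gel_control()`), then every protein column is divided
by the mean of the 5 wk normal condition so the reference sits exactly at
1 (`normalize_to_reference()`). Reference means are computed at the piece
level (after run averaging) and pooled across the three V1 regions; the
pooling granularity is a design choice — features are cross-regional, and
pooling keeps the normalization deterministic and simple. Replicate gel
runs are combined with an unweighted arithmetic mean; a piece's cell is
absent only when *every* run is absent. Rows with any remaining missing
cell are dropped from the analysis matrix (`assemble_matrix()`), and the
kept/dropped counts are reported — no value is ever imputed.

## Correlation networks

`condition_correlations()` pools each condition's samples across regions
and computes pairwise Pearson correlations among the 7 proteins.
Two-sided p-values come from the t-transform of R with n - 2 degrees of
freedom (the same math as the classical `rcorr` implementation, verified
against `cor.test` in the test suite). The Bonferroni denominator is the
21 unique pairs of one matrix: each condition's network is reported as
its own panel, so the correction is applied per matrix. Proteins are
seriated by average-linkage hierarchical clustering on d = 1 - r; ties
are resolved by the deterministic behaviour of `hclust`, and the fully
degenerate case (all distances equal) preserves the input order.

## PCA and the nine plasticity features

`run_pca()` centers columns (no scaling — all columns share the
normalized-OD scale) and applies SVD. The sign of each basis vector is
fixed by forcing its largest-magnitude entry positive, removing the sign
indeterminacy of the decomposition. Per-protein cos^2 is the squared
correlation between a protein column and each score dimension; each
protein's cos^2 sums to 1 across all seven dimensions because the
centered column lies in the span of the orthogonal scores.

The nine features are three mean-scaled sums — all-protein sum (/7),
glutamatergic receptor sum (/4), GABA-A receptor sum (/2) — and six
contrast indices of the form (a - b)/(a + b), including the E:I balance
(GlutR sum vs GABA_A_R sum). Indices are dimensionless, bounded in
[-1, 1] for nonnegative inputs, and invariant to rescaling all proteins
by a common factor. The conventional "a:b balance" names do not always
match the orientation of the printed formulas; the formulas (documented
in `compute_features()`) are authoritative and the names are labels only.

`screen_features()` correlates each feature with score dimensions 1-3,
Bonferroni-corrected over all 27 tests, and retains features with at
least one significant correlation. Correlations are computed on
sample-level scores (not condition means), matching the row count of the
assembled matrix. The E:I index is always carried into the phenotype
display because of its biological importance, but it joins the clustering
input only when it passes the screen.

## tSNE, k selection and subclusters

Features are z-scored before embedding: sums sit near 1 while indices
live in [-1, 1], and without standardization the sums would dominate
Euclidean distances. The embedding uses exact tSNE (theta = 0) with
perplexity 15 — suited to the roughly 110-sample matrices this design
produces — 1,000 iterations, and a fixed seed recorded in the outputs.
k-means runs on the 2-D tSNE coordinates (the embedding output is what
gets sorted into clusters; a caller can cluster the 8-feature matrix
directly by passing it to `kmeans_assign()`), with 50 restarts and labels
canonicalized by descending cluster size.

The number of clusters comes from an exponential elbow rule: best-of-
restarts WSS is computed for k = 2..9, WSS(k) = A exp(-k/tau) + C is fit
by least squares, and the elbow is taken at k* = 4 tau — after four time
constants the WSS curve has flattened to within ~2% of its floor.
Rounding of 4 tau is round-half-up, measured on the same k axis as the
fit. If the fit fails the largest second-difference elbow is used, with a
warning.

Subclusters are the condition-by-cluster groups with n >= 2 members and
strictly more than 20% of their cluster; labels carry region subscripts
(e.g. `MD 3_PM`) when members come from a strict subset of the three
regions. Subcluster similarity is the Pearson correlation between mean
feature vectors; with 8 features the p-values have 6 degrees of freedom —
a direct consequence of correlating short feature vectors, worth keeping
in mind when reading the significance calls. The Bonferroni threshold is
0.05 / C(m, 2); for 13 subclusters that is 0.05/78 ≈ 0.0006.

## Phenotype bands and the bootstrap comparison

`build_phenotype()` maps the three sums to a white-to-black grayscale
over [0, max across displayed groups] and the six indices to a fixed
red (-1) – yellow (0) – green (+1) gradient, clipped at the endpoints.
Both maps are pure monotone functions of the value.

`bootstrap_compare()` implements the Monte-Carlo procedure literally: a
Gaussian population of 1,000,000 points is simulated from the
subcluster's feature mean and SD, 100,000 resamples of size n (the
reference group's observation count) are drawn with replacement, the
two-sided 95/99/99.9% CIs of the resample means are formed, and the
comparison is flagged when the reference group's mean falls outside a CI.
The description of this procedure is genuinely ambiguous about which
group anchors the simulation and which mean is tested; the package
implements the literal reading and offers the mirrored convention via
`bootstrap_config(convention = "simulate_reference")`, with the reported
direction always describing the subcluster relative to the reference.
Multiple comparisons are handled by scaling the nominal levels
(0.05 -> 0.05/T over T = subclusters x 9 tests), which is equivalent to
widening the CIs and exactly reportable.

**Calibration caveat.** The CI width in this procedure reflects only the
resampling variability of a mean of n points around the subcluster's
*estimated* mean; the sampling error of that estimate itself is not
propagated. Under the null with equal group sizes the flag rate at the
nominal 95% level is therefore approximately
2 Phi(-1.96/sqrt(2)) ≈ 0.17 rather than 0.05 (the test suite includes a
null-calibration check that documents this). The procedure is faithful to
the published method and is anticonservative for equal-n comparisons;
users who need calibrated error rates should treat the flags as
descriptive, or use the larger-reference setting where the inflation is
smaller.

## The receptor decay-kinetics model

Receptor decay speed is set by subunit composition. For NMDARs, the
mixed GluN2A/GluN2B triheteromer decays in 50 ms, GluN2A-only receptors
in 36 ms, GluN2B-only in 333 ms; for GABA-A receptors the alpha1/alpha3,
alpha1-only and alpha3-only constants are 49, 42.2 and 129.0 ms. Given
subunit fractions (computed as OD_A / (OD_A + OD_B) from normalized
expression), the model maximizes mixed pairs — limited by the scarcer
subunit — and halves the remainder of the more abundant subunit to form
same-subunit pairs. The population decay time is the weighted average of
the three constants over that partition:

value = (pairs·tau_pair + leftover_mature·tau_mature +
leftover_immature·tau_immature) / (pairs + leftover_mature +
leftover_immature).

```{r kinetics}
population_kinetics(subunit_mix(0.35, 0.65), nmdar_params())
```

Because the denominator is always 1/2, the model reduces to a continuous
piecewise-linear function of the immature fraction b: for NMDARs,
36 + 28 b on [0, 0.5] and 566 b - 233 on [0.5, 1]; for GABA-A receptors,
42.2 + 13.6 g and 160 g - 31. These closed forms were re-derived by hand
and serve as the independent oracle in the tests (agreement to 1e-9 over
a 1,001-point grid). The prediction is bounded by the two pure-population
constants, increases strictly with the immature fraction, and depends
only on the subunit ratio. The published uncertainty ranges on the
constants are treated as fixed; `kinetics_params()` is the hook for
sensitivity analyses. This is population-level bookkeeping — it says
nothing about individual receptor channels.

Developmental and treatment trajectories are fit with
`fit_trajectory()`: exponential decay y0 + A exp(-x/tau), or a
4-parameter logistic whose asymptotes can be boxed to the receptor
constants. Non-convergence is reported as "no fit" rather than an error,
matching the practice of plotting only significant curve fits.

## The synthetic-data generator

`generate_dataset()` emulates the study's structure: six conditions
(5 wk normal, MD, RO, BD, ST-BV = 1-6 h of binocular vision, LT-BV =
1-4 d), three V1 regions with 113 tissue pieces in the bundled layout,
duplicate gel runs per piece, and occasional missing cells. Each run
record is an independent draw from the condition's multivariate Gaussian
(mean vector, correlation matrix, per-protein SD), truncated at zero
because an optical density cannot be negative. Missing cells are planted
at the piece level — a protein that is absent for a piece is absent in
every run — mirroring how a sample drops out of the assembled matrix.
A single master seed fans out to per-condition substreams, so a dataset
is bit-identical for a fixed (design, effects, seed).

The default planted effects encode the study's qualitative findings as
condition mean vectors (reference = 1): MD lowers GluN2A and raises
GluN2B and GABA-A alpha1 while decoupling glutamatergic from GABAergic
correlations; RO is dominated by excess GluA2 and GluN2A with lowered
overall expression; BD raises alpha1 with less GluN2A; ST-BV is an
intermediate transient; LT-BV is near-normal with the GABA-A receptor
sums lowered. The default per-protein noise SD is 0.1 — a realistic
replicate-to-replicate spread for control-normalized densities near 1 —
and every pair of condition means is separated by at least 3 noise SD in
at least one protein, so planted conditions are recoverable by the
clustering stages. The default missing rate of 0.005 drops a handful of
samples out of 113, as in the study. No dispersion estimates were
published, so these are stated modelling assumptions, not fitted values.

What the generator does *not* emulate: film densitometry and gel
artifacts, antibody stripping efficiency, nested run-within-piece
variance components (runs are exchangeable draws), within-animal
correlation beyond the condition structure, and any non-Gaussian tails in
real densitometry. Passing tests on synthetic data therefore demonstrate
that the pipeline's algorithms behave correctly under the declared data
model, not that the biological conclusions transfer to any particular
real dataset.

## Numerical choices and degenerate inputs

* Correlations with a constant column are undefined; they are reported
  as missing and excluded from significance calls.
* Rank-deficient PCA inputs are not an error — trailing variance
  fractions are zero; cos^2 of a zero-variance protein is NA.
* A feature index with zero denominator is NA and its phenotype band is
  rendered absent and flagged.
* A zero-SD subcluster cannot anchor the bootstrap simulation; the
  comparison degrades to an exact mean comparison with a warning.
* k-means with k = n short-circuits to singleton clusters (WSS = 0);
  empty-cluster restarts are handled by `stats::kmeans`'s restart
  machinery combined with best-of-50 selection.
* `round(4 tau)` uses round-half-up for reproducibility across
  platforms (base R rounds half to even).

## Problem sizes used by the tests

The test suite runs the full design (113 pieces, ~110 complete samples)
for the end-to-end properties: cluster recovery is averaged over 10
generator seeds; the planted-BD detection property uses 100 replicate
datasets with the reduced bootstrap (1e5-point simulation, 1e4
resamples); the null-calibration check uses 200 replicates at the same
reduced scale; the large-sample correlation check uses 5,000 records.
The full-scale bootstrap (1e6 / 1e5) remains the default for analyses
via `bootstrap_config()` and takes on the order of a minute for a
13-subcluster comparison grid.

## Known limitations

* The bootstrap comparison is anticonservative for equal group sizes
  (see above); this is inherent to the published procedure.
* Feature screening and clustering reuse the same samples; the
  phenotype significance flags are descriptive, not selective-inference
  corrected.
* The kinetics model ignores subunit combinations outside the modeled
  pair (e.g. receptors containing neither subunit) and treats the decay
  constants as exact.
* With only 8 features, subcluster correlations have 6 degrees of
  freedom; only near-perfect correlations clear the Bonferroni bar, and
  that is by construction of the method, not a bug.
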