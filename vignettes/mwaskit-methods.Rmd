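---
title: "Models and methods behind mwaskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mwaskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwaskit)
```

`mwaskit` implements the downstream arc of a case-control metagenome-wide
association study: from abundance tables to diversity, differential
abundance, metagenomic linkage groups (MLGs), co-occurrence networks,
stability-selected discriminative features, classifier evaluation,
species–metabolite association, and the exact statistics of a preclinical
mouse experiment. This vignette documents the models, the parameters that
matter, the numerical conventions, and the boundaries of what the tests
demonstrate.

## The synthetic cohort generator

Real cohort data for this class of study — two cohorts of stool
metagenomes (a discovery phase of 100 patients and 100 matched controls, a
validation phase of 40 + 40), serum metabolite panels, and mouse-arm
outcomes — cannot ship with a package. The generator
(`cohortDesign()` and the `simulate*()` family) emulates the statistical
structure every downstream stage assumes, together with the planted truth
needed for recovery testing:

* **Gene catalogs** (`simulateGeneCatalog`). Each co-abundance cluster
  carries one log-normal base trajectory across samples (log-scale sd 1, a
  heavy-tailed stand-in for metagenomic depth); member genes scatter
  around it with log-scale noise `noise_sd`, so the within-cluster Pearson
  correlation on log depth is `1 / (1 + noise_sd^2)` — about 0.96 at the
  default 0.2, comfortably above the 0.9 clustering threshold, and
  degrading realistically as `noise_sd` grows. A configurable fraction of
  clusters shifts its case mean by `effect_log2fc` log2 units.
  Annotations place `annotated_fraction` (default 0.95) of each cluster's
  genes on its true species above the species-vote thresholds, and give
  the rest sub-threshold decoy hits, so taxonomy voting is exercised with
  both signal and noise.
* **Taxon tables** (`simulateTaxonTable`). Log-normal species abundances
  closed to relative abundances per sample. Differential taxa get their
  own fraction (`frac_differential_taxa`, default 0.05) rather than
  reusing the cluster fraction: if a majority of taxa shifted together,
  closure would absorb the shift and the "differential" taxa would barely
  move in relative abundance — a compositional artifact worth simulating
  deliberately, not accidentally. Five differential species in a hundred
  mirrors the minority of differential species real cohorts report.
* **Metabolites** (`simulateMetabolites`). A linked metabolite is a
  monotone transform of a latent Gaussian correlated with the driver
  species' normal scores at `r = 2 sin(pi rho_S / 6)`, the inverse of the
  Gaussian rank-correlation identity, so the empirical Spearman
  correlation concentrates on `target_rho` regardless of the marginal
  transforms.
* **Mouse arms** (`simulateMouseExperiment`). Bernoulli aneurysm per the
  arm's incidence; Bernoulli rupture conditional on aneurysm (matching
  how rupture-rate denominators are reported: among aneurysm-positive
  animals only, e.g. n = 17 vs 9); symptom onset from a geometric
  distribution truncated to the 21-day observation window, the simplest
  discrete event-time law supported there; everyone else censored at day
  21. The default demo arms use incidence 0.85 vs 0.45 and conditional
  rupture 0.82 vs 0.22, the published arm-level rates.

One master seed is expanded into fixed per-stage substreams, so identical
`(design, seed)` pairs are bit-reproducible and any stage can be
regenerated independently.

What the generator does **not** emulate: read-level error, assembly
artifacts, zero inflation beyond what log-normal closure induces,
phylogenetic correlation among taxa, and covariate structure (age, sex,
medication). Passing recovery tests therefore demonstrate algorithmic
correctness under the assumed generative model, not robustness to every
pathology of real stool metagenomes.

## Diversity and ordination

Shannon diversity defaults to base 2 (the QIIME v1 convention; base is an
argument since the natural log is vegan's dialect). Bray-Curtis
dissimilarity delegates to `vegan::vegdist`. PCoA performs Gower
double-centering and eigendecomposition via classical metric scaling;
negative eigenvalues are reported but their axes dropped, with no
Cailliez/Lingoes correction, matching default vegan behaviour; explained
proportions are positive eigenvalues over the sum of absolute eigenvalues,
so they sum to at most one. ANOSIM is implemented in-package (vegan's R
statistic is used as a cross-check in the tests) because the permutation
loop needs seeded control: p uses the add-one correction
`(#{R* >= R} + 1)/(n_perm + 1)`, which never returns an exact zero — the
right behaviour when p-values feed BH adjustment downstream. Rarefaction
is genuine Monte-Carlo subsampling without replacement; its mean is tested
against the hypergeometric closed form.

## Differential abundance

Per-feature two-sided Wilcoxon rank-sum with midranks, BH across features,
direction from group means of relative abundance (medians available). The
normal approximation applies the tie-corrected variance and, by default,
no continuity correction — the `wilcox.test(correct = FALSE)` large-sample
path common in metagenomic pipelines; the correction is a flag. Exact mode
uses the exact rank-sum null distribution and falls back to the normal
path (with a warning) when ties make the exact distribution unavailable.
A prevalence pre-filter exists but defaults to off.

## MLG construction

The clustering is canopy-style co-abundance clustering on log-transformed
depths: genes are visited in input order, each unassigned gene seeds a
canopy, the canopy absorbs genes correlating at or above the threshold
with its running centroid until membership stabilises, and canopies whose
centroids still correlate above threshold merge. The log transform uses a
pseudocount of half the smallest nonzero depth — large enough to avoid
minus infinity, small enough to preserve rank structure. Determinism given
input order is asserted by test. The `> 50 genes` rule is strict: a
perfect 50-gene cluster is not an MLG and the tests pin that boundary.
Taxonomy voting reads every printed threshold as inclusive (`>=`): 90% of
members at 95% DNA identity and 70% query overlap for species, 80% at
85%/85% DNA/protein identity for genus; ties break by higher qualifying
fraction, then lexicographic name. MLG abundance is the length-weighted
mean of member depths, which is linear in the member abundances; the
alternative reading (mean of raw depth) differs only by a scale factor
under the catalog's length normalisation, and the weighted form is adopted.

## SparCC networks

The basis-correlation estimator solves the sparsity-assumption linear
system for basis variances from the row sums of the log-ratio variance
matrix, iteratively excluding the strongest pair above the exclusion
threshold (default 0.1, up to 20 iterations, both from the original SparCC
release) and keeping every feature attached to at least three included
partners so the system stays solvable. Integer counts are resampled from
per-sample Dirichlet(count + 1) posteriors (20 draws, median aggregation);
fractional input is estimated in a single pass. Pseudo p-values permute
every feature independently and use two-sided extremity `|rho|` with the
add-one correction, since networks report both positive and negative
edges and an exact-zero p would break BH. Edge filters are strict
inequalities: correlation above 0.5 (or below −0.5) and adjusted p below
0.01, so a correlation of exactly 0.5 is dropped.

## Stability selection

PLS-DA is NIPALS PLS1 against the centered 0/1 dummy response; prediction
thresholds the continuous score at the class-code midpoint. The
Monte-Carlo machinery draws `N` class-stratified half-samples (`M = n/2`),
collects the per-resample coefficients, and computes
`c_j = beta_j / s(beta_j)` with the mean over resamples as `beta_j` — the
only reading under which `s(beta_j)` with its `N − 1` denominator is a
standard deviation. `N = n^2` is statistically comfortable but quadratic
in cohort size (40 000 fits at n = 200), so `N` defaults to
`min(n^2, 2000)` with the cap configurable back up to `n^2`. Resampling is
stratified by class so every fit sees both labels. Selection scans
`|c_j| > cutoff` over an ascending grid against stratified k-fold
(default 4) cross-validated accuracy; ties resolve to the larger cutoff,
i.e. the sparser model. Variables with exactly zero coefficient spread get
an undefined `c_j` and are excluded. Components default to 2.

One honest caveat: `c_j` is exactly invariant to rescaling *all*
predictors by one positive constant, and to rescaling the predictor of a
single-variable model, but rescaling one column of a multi-component PLS
rotates the latent directions, so per-column invariance holds only
approximately. This is a property of PLS itself (it is why autoscaling
conventions exist), and the tests assert the exact variants.

## Classifier evaluation

The evaluation protocol — 30 random trials of stratified 4-fold
cross-validation, out-of-fold continuous scores averaged per sample, ROC
by threshold sweep with tie grouping, AUC by trapezoid (provably equal to
the tie-averaged Mann-Whitney `U/(n1 n2)`, asserted against the rank-sum
module), percentile bootstrap interval from class-stratified resampling —
is the module's contribution; the learner is a pluggable `fit`/`score`
contract with a random-forest default (library hyperparameters) and a
PLS-DA alternative, reflecting that either learner can sit inside the same
protocol. Percentile rather than BCa intervals: the simplest procedure the
name "bootstrap" promises.

## Species–metabolite association

Spearman with midranks; exact permutation p for n ≤ 9 without ties, the
t approximation with n − 2 degrees of freedom otherwise. The heatmap masks
pairs with `|rho| < 0.4` (strictly: 0.4 exactly is shown) and marks
significance at the looser/stricter levels on BH-adjusted values by
default — the study-wide convention — with raw-p marking behind a flag
since display conventions differ. Rows and columns are ordered by
average-linkage clustering on correlation distance `1 − r`; the linkage is
a parameter because both average and Ward appear in this literature.
Constant rows have undefined correlation and get distance 1 with a
warning.

## Preclinical statistics

Fisher's exact test uses the point-probability two-sided rule (the
`fisher.test` convention). On the arm-by-outcome tables reconstructed from
printed percentages and group sizes — 17/20 vs 9/20, 14/17 vs 2/9, 8/20 vs
18/20, 2/8 vs 14/18, 9/20 vs 18/20 — it reproduces the published 0.019,
0.009, 0.002, 0.026, and 0.006. One published rupture comparison (44% vs
83%, n = 9 vs 18, reported p = 0.026) does not match the point-probability
two-sided Fisher on its reconstructed table (enumeration gives ≈ 0.07);
the test variant behind that single value is unclear, and the package
flags rather than chases it. Kaplan-Meier curves and the Mantel-Cox
log-rank restrict to aneurysm-positive animals, per the figure-legend
denominators; a no-event comparison returns p = 1 with a warning instead
of failing. Hypergeometric enrichment is upper-tail with BH across terms,
and is tested against complete subset enumeration on small universes.

## Problem sizes and what the checks show

The package-level acceptance checks run at desk scale: differential-taxon
recovery at n = 100 + 100 with 100 species and 5 planted effects; MLG
recovery on 10 planted 60-gene clusters among 700 genes at `noise_sd`
0.2; SparCC recovery of a planted 0.8 basis correlation at n = 200 among
50 features, with null calibration at 20 features and 100 permutations;
stability selection over 20 replicate cohorts of 50 variables at n = 100
with `N` = 2000 resamples; and type-I calibration of ANOSIM, log-rank,
and ANOVA at 1000 simulated nulls each. These sizes make the whole suite
run in well under a minute while keeping the Monte-Carlo error bands
(three standard errors throughout) meaningful. Every number the README
shows was produced by executing the code shown next to it.

## Known limitations

* The generator's independence assumptions (taxa, genes outside clusters,
  unlinked metabolites) are stronger than real data; correlations induced
  purely by closure are present, other ecological covariance is not.
* SparCC's sparsity assumption fails on densely correlated communities;
  the estimator inherits that, and the exclusion heuristic only mitigates
  it.
* PLS-DA stability selection is reported for two components and unscaled
  predictors; heavily skewed abundance distributions may warrant a log or
  rank transform upstream, which the package leaves to the caller.
* The pipeline runner orchestrates the synthetic demonstration; analysing
  a real cohort means calling the stage functions directly on imported
  tables (`readMatrixTSV`, `AbundanceTable`), which is the intended use.
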