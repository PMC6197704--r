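---
title: "Predicting polygenic risk from grey-matter patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting polygenic risk from grey-matter patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prsmvpa)
```

## The problem

A polygenic risk score (PRS) summarizes the common-variant genetic
liability an individual carries for a disorder: a weighted sum of
effect-allele dosages, with weights taken from an independent discovery
genome-wide association study. Genetic risk for psychiatric disorders is
expected to act diffusely on brain development, so its structural
correlates are more plausibly a *distributed, covarying pattern* of
grey-matter differences than a focal lesion. prsmvpa implements both
sides of that argument on the same data: a mass-univariate voxelwise
regression with family-wise-error control, and a multivariate kernel
regression that predicts each subject's PRS from the whole grey-matter
map at once, with significance assessed by permutation.

Because the cohorts such studies rest on are private, the package ships
a seeded synthetic cohort generator that emulates every input: block-LD
genotypes, discovery summary statistics, smooth 3D grey-matter maps
carrying a plantable PRS-linked pattern, and a demographic covariate
table for a two-study case-control sample (69 depression patients + 70
controls; 33 bipolar patients + 41 controls; 213 subjects, 111 of them
controls). The generator is first-class, tested code: every statistical
guarantee claimed for the pipeline is demonstrated against it.

## Polygenic scoring

`ld_clump()` performs p-value-informed greedy clumping against the
analysis panel's own dosages: SNPs are processed in ascending p (ties
broken lexicographically by p, position, id); each index SNP removes
unprocessed neighbours on the same chromosome within a 200 kb window
whose squared dosage correlation exceeds r² = 0.25. The extended MHC
region is excluded first (default chr6:25–35 Mb, deliberately wide
because of its long-range LD; configurable). `threshold_select()` then
keeps clumped SNPs with p strictly below 0.1 — ties at the boundary are
excluded, a documented convention. `allele_align()` reconciles the
panel's counted allele with the discovery effect allele (betas are
negated when the dosage counts the other allele; strand-ambiguous A/T
and C/G pairs are dropped with a warning), and `compute_prs()`
accumulates `sum_i beta_i * dosage_ij` with per-SNP mean imputation of
missing dosages. Sum scoring is the default, with mean scoring
available: downstream analyses are invariant to that affine difference,
and published pipelines do not always state which they used.

Score-level descriptives mirror common practice: z-standardization to
the pooled controls' mean and SD, one-way ANOVA across the three
diagnostic groups (df (k−1, N−k); (2, 210) at N = 213), pairwise Welch
t-tests when the F test is significant, and pairwise score correlations
with Benjamini–Hochberg adjustment.

## Image features

Maps are smoothed with a separable Gaussian kernel parameterized by its
full-width-half-maximum: per-axis sigma in voxels is
`(fwhm_mm / voxel_size_mm) / (2 sqrt(2 ln 2))` (1.699 voxels for 8 mm
FWHM on a 2 mm grid). The kernel is truncated at 4 sigma and
renormalized to unit sum; boundaries use nearest-edge replication, which
avoids mass-leakage artifacts at the brain edge. `vectorize()` flattens
in-mask voxels in a fixed x-fastest raster order — the first grid axis
varies quickest — recorded in the feature object so weight maps can be
re-projected reproducibly (`devectorize()`). Intracranial volume is the
voxel-volume-weighted sum of a total-tissue map. Modulated versus
unmodulated preprocessing is carried as metadata only; both analyses
consume whichever set is supplied.

## Relevance vector regression

The multivariate model is Tipping-style sparse Bayesian regression over
the design `[bias | K]`, with K the linear kernel of the (residualized)
feature rows. Each basis has an independent zero-mean Gaussian prior
with precision `alpha_i`; iterative re-estimation alternates the
posterior update

    Sigma = (Phi' Phi / sigma^2 + diag(alpha))^-1,
    mu    = Sigma Phi' y / sigma^2,

with the hyperparameter updates `gamma_i = 1 − alpha_i Sigma_ii`,
`alpha_i ← gamma_i / mu_i²` and
`sigma² ← ||y − Phi mu||² / (n − sum gamma)`. Most precisions diverge;
bases with `alpha > 1e9` are pruned (never the bias), and the surviving
training samples are the relevance vectors. We use the original
iterative scheme rather than the later fast sequential variant: at
n ≈ 200 it is simple and fast enough, and it matches the lineage of the
neuroimaging toolboxes that popularized RVR. Defaults: `alpha_init =
1/n²` and `sigma²_init = 0.1 var(y)` (scale-free), convergence at
`max |Δ log alpha| < 1e-6`, at most 2000 iterations. The marginal
log-likelihood is tracked every iteration and is non-decreasing up to
numerical tolerance. The kernel is not mean-centered — the explicit
bias basis absorbs offsets; centering is a documented unknown in the
reference toolchain, and the uncentered choice is the default here.
Posterior covariance solves use a symmetric inverse with a relative
jitter fallback of `1e-10 · trace`, needed when leave-one-out folds
contain near-duplicate subjects. The inner loop is implemented in C++
(RcppArmadillo) because the permutation machinery refits the model tens
of thousands of times.

For a linear kernel the fitted function is linear in voxel space:
`backproject_weights()` returns `w = sum_j mu_j x_j` over the active
training rows, and the identity `yhat(x) = <w, x> + bias` is verified
against the dual form in the tests.

With the precisions frozen at a common value and pruning disabled, the
fit reduces exactly to kernel ridge regression with penalty
`sigma² alpha` — a closed-form equivalence the test suite asserts to
1e-10, which pins the linear algebra independently of the
hyperparameter dynamics.

## Cross-validation, confounds, permutation, FDR

`make_folds()` implements leave-one-subject-out and shuffled k-fold
splitting (first k−1 folds of size `floor(n/k)`, the last fold absorbs
the remainder: 213 subjects in 10 folds gives nine folds of 21 and one
of 24). Confounds — age, sex, diagnostic status, study, intracranial
volume — are regressed out of the *training* features per voxel, and
the training coefficients are applied to the test rows; nothing is
refit on test data, so no information crosses the fold boundary. The
target is never residualized.

Significance uses a label-permutation test: the target is shuffled and
the entire cross-validation re-run. Because confound residualization
never involves the target, the per-fold residualized features and
kernels are computed once and reused across permutations — a
mathematically identical, roughly thousand-fold cheaper arrangement.
One-sided p-values are `max(1, #{null r ≥ observed r}) / n_perm` for
the correlation (and the mirror-image count for the error), so the
smallest attainable p is `1/n_perm` — 0.001 at the conventional 1000
permutations. The estimator deliberately uses `count/n_perm` with a
floor rather than `(count+1)/(n_perm+1)`, matching the floor convention
of the toolchain being emulated. Across the four disorder scores,
p-values are Benjamini–Hochberg adjusted per metric (m = 4), since the
scores are correlated and four multivariate analyses are run.

The normalized MSE divides the mean squared prediction error by the
**squared** range of the actual target. The phrase "normalised to the
range" is genuinely ambiguous between plain and squared range and
between actual and predicted targets; squared-range scaling of the
actual target makes the quantity dimensionless and comparable across
scores, and the plain-range convention is available via
`eval_metrics(range_power = 1)`.

Region summaries divide the mean back-projected weight map by atlas
label: a region's contribution is `100 · Σ|w|` over its voxels divided
by `Σ|w|` over all in-mask voxels, with unlabeled in-mask voxels
reported as an explicit pseudo-region so contributions always sum
to 100. The *expected ranking* is the mean of a region's per-fold rank
(descending contribution, ties broken by region id): agreement with the
overall rank indicates the weight map is stable across folds. These
summaries are for visualization — in a multivariate model all voxels
contribute jointly and no voxel-wise inference is performed on weights.

## Univariate voxelwise regression

`fit_voxelwise_glm()` runs ordinary least squares per voxel with the
PRS as the effect of interest and the same nuisance covariates; both
association signs are testable. Family-wise error is controlled by
max-statistic permutation in the Freedman–Lane scheme: the data are
residualized against the nuisance model, residual rows are permuted,
the nuisance fit is added back, and the full model is refit. Voxel-wise
corrected p-values come from the null of the maximum |t|; cluster-level
p-values from the null of the largest suprathreshold cluster at a
two-sided cluster-forming threshold of p < 0.001, with 26-connectivity
and a reporting floor of k = 20 voxels. Permutation was chosen over
random-field theory deliberately: it is exact under exchangeability and
needs no smoothness estimation. The design matrix is internally scaled
to unit column norms (the t statistic is scale-invariant), so nuisance
columns on wildly different scales — intracranial volume in mm³ next to
a 0/1 sex indicator — do not degrade the normal-equations solve.

## The synthetic cohort: what it does and does not emulate

*Genotypes.* SNPs come in independent blocks; within a block every pair
of latent haplotype variables shares correlation `within_block_corr`
(default 0.7), and dosages arise by thresholding two independent latent
haplotypes at each SNP's Hardy–Weinberg quantile for a MAF drawn
uniformly from (0.05, 0.5). This thresholded-Gaussian-copula
construction reproduces the LD that matters for clumping without
coalescent machinery. Block coordinates (≤150 kb span, 2.5 Mb spacing)
keep clumping windows inside blocks.

*Summary statistics.* Generated analytically as true beta plus noise
with SE `1/sqrt(2 N maf (1−maf))` at a discovery sample size of 50,000,
with two-sided Wald p-values — the same marginal distribution a
simulated discovery cohort would give, orders of magnitude faster.
20% of SNPs are causal per disorder.

*Images.* Each subject's map is a shared template plus smoothed white
noise (8 mm FWHM, unit SD in-mask), covariate-linked confound fields,
and the planted pattern scaled by the subject's standardized genetic
score. The pattern is a sparse-support sum of signed Gaussian blobs
inside an ellipsoidal mask. The signal scale is calibrated so the
correlation between the score and the pattern's projection on the maps
equals `signal_r` (default 0.5). Confound fields are orthogonalized
against the planted pattern: a covariate effect must not masquerade as
the PRS-linked signal, and without that constraint confound
residualization would *remove* nuisance variance along the pattern and
silently inflate the achievable prediction correlation above the dial's
setting. `signal_r` therefore indexes the effective signal strength of
the confound-adjusted analysis. Its default is chosen for testability:
the one comparable published estimate of a PRS–grey-matter association
at n = 213 (r ≈ 0.2) would require far larger simulated cohorts to
distinguish from null at desk scale.

*Covariates.* Group-specific age distributions clipped to 18–68 years,
group-specific sex frequencies, lognormal intracranial volume around
1.5 L, study membership derived from the group.

What the generator does **not** emulate: genotyping chips, imputation,
QC, population structure; tissue segmentation, nonlinear registration,
template building, modulation physics; scanner differences beyond a
study covariate; spatial autocorrelation structure of real grey matter
beyond stationary Gaussian smoothing. Passing tests therefore show the
*pipeline's* statistical properties (calibration, leakage-freedom,
recovery) under a controlled model, not that real cohorts would yield
any particular effect size.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately small
scale, chosen as the smallest sizes at which each property is
informative: smoke cohorts of 40 subjects on 8³ grids for permutation
floor and size calibration (200–1000 permutations; 20 null cohorts for
the size check, 100 replicates for the univariate familywise check),
and the full 213-subject cohort on a 12³ grid with 10-fold CV and
100–200 permutations for recovery (20 seeds). Ten-fold CV is used where
the permutation machinery is exercised repeatedly; leave-one-subject-out
is the default for single analyses. Degenerate inputs are handled
explicitly: constant targets reject in `eval_metrics()` and collapse
RVR to its bias; zero-variance SNPs are excluded from clumping with a
warning; an all-missing SNP is an error; a perfect voxel fit caps |t|
at 1e10 and flags the map; a vanishing degrees-of-freedom denominator
in the RVR noise update clamps and flags non-convergence.

## Known limitations

- The RVR implementation prunes monotonically; bases are never
  re-introduced, as in the original iterative scheme.
- Permutation exchangeability is assumed across the whole sample;
  within-study restricted permutation is not implemented.
- The univariate cluster-forming threshold is two-sided by default,
  which differs from per-contrast one-sided conventions in some
  toolboxes (negate the contrast for a one-sided map).
- PRS-by-diagnosis interactions and alternative sparse learners are out
  of scope by design.
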