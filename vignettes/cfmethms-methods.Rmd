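---
title: "Models and methods behind cfmethms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cfmethms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cfmethms` analyses low-coverage plasma cell-free DNA (cfDNA) bisulfite
sequencing in multiple sclerosis (MS) cohorts: differential methylation and
DMR calling from per-CpG counts, fragment-level tissue-of-origin
deconvolution, a longitudinal mixed-model screen for prognostic regions, a
methylation-based progression risk score (MBPRS) with survival
stratification and permutation controls, and a leakage-safe classification
harness. This vignette explains the models, the tunable parameters, and the
design choices made where the design was genuinely open; the README shows a
worked example.

## Data model and conventions

All genomic coordinates are 0-based half-open, everywhere: BED input is
native, 1-based inputs must be converted at the boundary, and a CpG at
`position == end` lies outside an interval. Only autosomal CpGs enter any
analysis. A `CpGCountMatrix` stores methylated and total read counts per
CpG and sample; `total == 0` encodes "no coverage", so every downstream
filter operates on coverage rather than sentinel values. Region-level
methylation is the read-weighted density: summed methylated counts over
summed totals within the interval, missing when no read covers the region.
Fragment records (PAT-like) carry the binary methylation calls of the CpGs
on one sequenced molecule plus a multiplicity.

## Per-CpG beta-binomial test and DMR calling

At each CpG the methylated counts are modelled as beta-binomial with a
logit-linear mean (intercept + group + optional covariate, by default sex)
and a site-level intra-class correlation `rho`. Counts are overdispersed
relative to binomial at low coverage because fragments sample a mixture of
cell types and alleles; `rho` absorbs this.

Three numerical choices matter and were validated on simulated null
cohorts (20 vs 20 samples, 10 reads/CpG, `rho = 0.1`):

* **Dispersion estimation.** `rho` is estimated under the *full* model by
  maximizing the Cox–Reid adjusted profile likelihood, then held fixed
  while the full and reduced mean models are maximized. A plain joint ML
  estimate is biased downward (anticonservative test); estimating `rho`
  under the reduced model instead is calibrated under the null but
  collapses to `rho -> 1` under strong group separation, absorbing the
  effect being tested. The Cox–Reid adjustment handles both regimes.
* **Reference distribution.** The likelihood-ratio statistic is referred
  to `F(1, n - p)` (covered samples minus mean parameters), the
  quasi-likelihood-style small-sample reference, which converges to the
  asymptotic chi-square(1) as `n` grows. At cohort-scale `n` the
  chi-square reference runs measurably liberal.
* **Degenerate sites.** Sites with fewer than two covered samples per
  group are recorded untested; sites with no variation (all counts 0 or
  all fully methylated) get `LRT = 0`.

Raw p-values of adjacent CpGs are combined by a weighted Stouffer sum over
a centred window of tested sites, with the window sum's variance inflated
by the empirical lag-autocorrelation of the z-scores. One window size is
applied to all sites. When no window is given it is selected from the data
as 1 plus the run of consecutive significantly positive autocorrelation
lags (capped at 100): under a global null the selection collapses to
window 1 and the combined p-values equal the raw ones, keeping the
combination calibrated; under planted signal the window grows to roughly
the DMR width. A per-site scan minimum over many window sizes was
deliberately rejected: it is a scan statistic and cannot be uniform under
the null.

DMRs are maximal runs of consecutive tested CpGs with combined `p < 0.1`,
consistent direction (sign of the group density difference; zero
difference breaks a run), and inter-CpG gaps of at most 500 bp (the merge
distance is exposed; the upstream literature is silent, and 500 bp matches
typical cfDNA fragment scales). Untested CpGs break runs — they never
bridge two DMRs. A candidate region is retained when its minimum site
q-value (Benjamini–Hochberg over combined p-values) is below 0.1 and its
absolute mean density difference exceeds 0.1. Whether the q filter applies
per site or per region is ambiguous in the source methods; the minimum
per-site q within the DMR is used and documented here.

## Region features: filtering, imputation, SVD

Regions with at least 80% missing samples are dropped (strict threshold).
Remaining missing cells are kNN-imputed: a missing value is the mean of
the `k = 10` nearest regions (Euclidean distance over shared observed
samples, rescaled by the observed fraction), using only neighbours
observed for that sample, clipped to `[0, 1]`. Imputation of a complete
matrix is the identity. Regions are then standardized and decomposed by
SVD; sample scores of the top components are the features. Components are
sign-oriented so the largest-magnitude score is positive (SVD is
sign-indeterminate; a convention makes outputs reproducible). With
`k = "elbow"` the retained rank is the largest second difference of the
variance-explained curve over the first 50 components; per-comparison
defaults of 6 (subtype contrasts) and 4 (disability contrasts) mirror the
published choices and are overridable.

Chromatin-state enrichment compares a query region set against random
intervals matched per query region on chromosome and length (uniform
start), with a two-sided Fisher exact test per state and BH correction
across states. The reported odds ratio is the sample odds ratio of the
2x2 table. Overlap means at least one intersecting base pair by default
(a fraction-of-region alternative is exposed). Matched randoms may overlap
each other; sidedness of the published test is unstated, so two-sided is
used with the direction reported separately.

## Fragment-level U/X/M deconvolution

A fragment with at least `min_cpgs = 3` CpG calls is classified by its
methylated fraction `f`: U (mostly unmethylated) if `f <= 0.25`, M if
`f >= 0.75` (both boundaries inclusive toward the extreme classes), X
otherwise; shorter fragments are ineligible. These thresholds are the
package's documented defaults (the upstream tool's defaults are not
restated in the source) and are configurable. Per marker, the U-fraction
is the multiplicity-weighted share of U among eligible fragments; markers
with no eligible fragment are missing and are excluded from the fit rather
than imputed. Cell-type proportions solve a non-negative least squares fit
of the observed marker U-fractions against the atlas reference columns
(via `pracma::lsqnonneg`), normalized to sum to one.

The coverage simulation mirrors the sequencing-depth power analysis: a
pooled fragment set of known effective coverage is binomially thinned to
each target coverage (0.01x to 12x by default), deconvolved, and the
spread of the estimates across 100 repetitions summarized. Group
differences in proportions use the one-sided Mann–Whitney U test.

## Longitudinal prognostic screen and the MBPRS

Disability is the Patient Determined Disease Steps (PDDS), an ordinal 0–8
patient-reported scale; 4 means needing ambulatory assistance. Observed
trajectories are linearly interpolated on a 50-day grid within day 0–2000
for fixed-horizon outcome extraction only; the mixed model itself uses the
raw visit data (the model indexes observations, and interpolation would
manufacture correlated pseudo-observations). A config switch allows the
interpolated variant.

Candidate regions are maximal runs of CpGs covered in every
region-defining sample, merged across gaps of at most 300 bp; samples
missing more than 90% of the final regions are excluded.

Per region, patients are dichotomized High/Low at the cohort median of
baseline region methylation (ties to Low), and

```
PDDS_ij = b0 + b1 t_ij + b2 G_i + b3 (t_ij x G_i) + covariates_i + u_i + e_ij
```

is fitted by REML with a per-patient random intercept; covariates are age,
sex, race, disease duration, DMT type, DMT effectiveness and follow-up
duration (categorical covariates with fewer than two observed levels, or
with missing values, are dropped with a warning). The reported test is the
Satterthwaite-approximated p-value of the interaction `b3` (PDDS/day).
Because the screen fits hundreds of thousands of regions across
permutations and replicates, the solver is a dedicated random-intercept
REML routine using the closed-form block inverse of `I + theta * J`,
profiled over the variance ratio, with the Satterthwaite degrees of
freedom computed from the numerical REML information matrix; it reproduces
`lmerTest`'s estimate, standard error, df and p-value to ~1e-6 on
fixtures, and `lmerTest` serves as the independent oracle in the test
suite. When the random-intercept variance collapses to the boundary the
normal reference is used and flagged. Bonferroni adjustment runs across
converged regions only (the denominator is reported); Bonferroni is
implemented because it is the stated procedure, with the threshold
exposed as `alpha = 0.01`.

Regions are ranked by `|b3| * -log10(adjusted p)`. The top-`k` (default
100) significant regions define the MBPRS: a weighted sum of baseline
methylation with weights `b3`, split High/Low at the median score (ties to
Low). Progression-free survival counts the first visit with PDDS >= 4 as
the event, censored at the last visit; patients already at PDDS >= 4 at
baseline cannot progress under this definition and are excluded by default
(an immediate-event alternative is exposed). The High/Low split is tested
by the standard two-group log-rank test (`survival::survdiff`).

Two controls guard the score. First, 1,000 sets of random intervals
matched on chromosome and length replace the selected regions, the
original weights are re-applied, and the log-rank test re-run; the
empirical p is `(1 + #{perm p <= observed}) / (n_perm + 1)`, with
degenerate permutations counted as non-extreme (conservative). Second, the
bottom-`k` least informative regions are scored the same way. Ranking ties
for the bottom set are broken toward larger adjusted p and then smaller
`|b3|`: with in-sample-estimated weights, any region whose methylation
correlates even slightly with the outcome leaks signal into a weighted
sum, so the control must be drawn from the genuinely uninformative end.
The bottom set deliberately applies no significance filter — in moderate
cohorts the significant set is small, and a significance-filtered "bottom"
would coincide with the top set and could not act as a control.

## Classification harness

Folds are stratified: each class is shuffled and dealt round-robin, so
per-fold class counts deviate from the global ratio by at most one sample;
plans support repeats (e.g. 5 folds x 100 repeats for the prognosis
setting). Feature discovery — DMR calling or Mann–Whitney tissue-of-origin
selection at per-comparison cutoffs (0.05 / 0.1 / 0.2) — runs inside each
training fold; test samples only ever pass through the frozen feature
definition, with missing values becoming zeros at apply time. SVD feature
pipelines compute loadings on the training fold and project the test fold
onto them. Model families (L2/elastic-net logistic via glmnet, linear/RBF
SVM via e1071, gradient-boosted trees via xgboost) and the published
per-comparison hyperparameters ship as named presets
(`ms_vs_control`, `pms_vs_rrms`, `arrms_vs_srrms`, `severity`,
`prognosis`) — they are experiment settings, not behavior. AUC is the
Mann–Whitney rank statistic with mid-ranks. The harness's central
regression test is the leakage check: with labels permuted, the mean
cross-validated AUC must be statistically indistinguishable from 0.5.

## The synthetic cohort generator

The generator produces data with exactly the statistical structure the
pipeline assumes, which is what the test suite and acceptance checks
exercise. Counts: totals are Poisson with mean coverage 1.5 reads/CpG by
default (the low-coverage cfDNA operating point; differential-methylation
calibration runs use 10x, and the prognosis cohort uses 10x because the
candidate-region step keeps fully observed loci, which are biased toward
higher depth); methylated counts are beta-binomial with intra-class
correlation `rho = 0.1` — the real cohort's overdispersion is not
published, so this default is an explicit placeholder — around a bimodal
baseline (equal mixture of Beta(2, 8) and Beta(8, 2), modes near 0.12 and
0.88, avoiding the degenerate extremes where no count model is
identifiable). Planted DMRs are logit-scale shifts (default 1.4, giving
density differences near 0.3) at mid-range baseline CpGs (Beta(5, 5)),
where regulatory-region DMRs live. Fragments are drawn cell type first
(from the mixture), then marker, then per-CpG Bernoulli calls at the cell
type's marker methylation; the synthetic atlas is unmethylated (0.05) in
the target type and methylated (0.92) elsewhere, and its reference
U-fractions are computed in closed form from the fragment-length
distribution so that deconvolution of noiseless data is exact.
Trajectories follow the mixed model above with defaults `b0 = 1.5`,
`b1 = 3e-4`/day, `b3 = 2e-3`/day, `sigma_u = sigma_e = 0.5`, eight visits
about 250 days apart with +/-20% jitter (so interpolation is exercised
honestly), rounded and clamped to the ordinal 0–8 scale. Covariate effects
default to zero so null-calibration tests are exactly null. A latent
per-patient progression factor `h_i` ties the two data levels together:
planted prognostic regions shift methylation by 2 logit units between
`h` groups, and `h` drives the trajectory interaction — so each planted
region's median split recovers `h` with small error at the simulated
depth.

What the generator does not emulate: sequencing error, incomplete
bisulfite conversion, fragment-length biology, batch effects, correlated
missingness, multiple independent progression factors, or informative
visit schedules. Passing tests demonstrate internal statistical
correctness of the pipeline under its own assumptions, not performance on
real cfDNA data.

## Problem sizes and reproducibility

The acceptance checks run at the documented study conditions: 2,000 null
CpGs for calibration; 50 planted DMRs among 10,000 CpGs (20 vs 20 at 10x)
for recovery; 100 repetitions per coverage on a 0.01x–12x grid for the
deconvolution power curve; 200 planted and 20 x 500 null regions for the
mixed-model screen; 50 replicate cohorts (60 patients, 2,000 regions, 20
prognostic) with 99 matched-interval permutations each for the MBPRS; and
20 label permutations for the leakage check. Every stochastic step is
seeded; `scripts/acceptance.R --seed S` derives all stage seeds from `S`,
and identical seeds give byte-identical outputs.

## Known limitations

The per-CpG test assumes a common dispersion across samples at a site; the
neighbour combination assumes stationarity of the z autocorrelation; the
mixed model uses a single random intercept (no random slopes) and treats
the ordinal PDDS as continuous, as the source analysis does; the
permutation control re-uses the observed weights rather than re-screening
per permutation (matching the published procedure, and keeping the control
specific to region placement); and candidate-region counts from the real
cohort (millions of regions) are not reproducible at package scale —
documented sizes stand in for them.
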