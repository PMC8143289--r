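---
title: "locrad: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{locrad: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`locrad` classifies prostate lesions as clinically significant or
non-significant cancer from a single MR sequence: lesion ROIs on high
b-value diffusion-weighted volumes (or coregistered ADC maps). This
vignette documents the statistical model, the choices made where several
reasonable conventions exist, what the synthetic phantom cohort does and
does not emulate, and the limitations we know about.

## The feature model

The premise is that malignancy grade expresses itself less in the
absolute lesion signal than in the *spatial organization* of the signal:
more aggressive tumors are more heterogeneous (local cellularity varies
from patch to patch) and more asymmetric (the local intensity
distribution grows a heavy right tail). Plain first-order statistics over
the whole ROI are blind to spatial structure, so the extractor works at
two scales:

1. **Local scale.** For each ROI pixel, seven first-order statistics of
   the square in-slice patch centred on it: mean `m`, median `M`,
   skewness `s`, excess kurtosis `k`, interquartile range `iqr`,
   coefficient of variation `cv`, Shannon entropy `e`. The patch side is
   derived from the pixel spacing, `side = 2 * floor(5 mm / spacing) + 1`
   clamped to ≥ 3, so the patch explores at least ~0.5 cm from the
   centre pixel in each in-plane direction (~1 cm² of tissue). At the
   1.41–1.67 mm spacings typical of prostate DWI this gives 7 and 5
   pixels respectively. We use the floor (not the ceiling) of
   `5/spacing`: it is the only simple rule that keeps the side within the
   5–7 pixel band across that spacing range (the ceiling gives 9 pixels
   at 1.41 mm). Patches are 2D because slices are 3 mm thick with a 3 mm
   gap: through-plane neighbours are 6 mm away and not comparable to
   in-plane ones. Windows are truncated at image borders, and patch
   membership is *not* restricted to the mask — surrounding context
   pixels contribute, since the local statistic describes the tissue
   neighbourhood of the pixel, not the lesion interior alone.
2. **Global scale.** Each of the seven local-statistic distributions,
   pooled over all ROI pixels of all slices and all lesions of the
   patient (the unit of classification is the patient, not the lesion),
   is summarized by twelve statistics: the same seven, plus the maximum,
   standard deviation `sigma`, median absolute deviation `mad`, and the
   mean `m90th` and median `M90th` of the last decile (all values at or
   above the empirical 90th percentile). That yields 7 × 12 = 84 named
   features, `<local>_<global>`, e.g. `m_sigma` = how much the local mean
   varies across the lesion, `s_M90th` = how skewed the most skewed
   patches are.

### Estimator conventions

No universal conventions exist for these estimators, so the package fixes
them explicitly (and the unit tests freeze them):

- quantiles (median, IQR, 90th percentile) are linear-interpolation
  empirical quantiles (R type 7);
- skewness is the bias-uncorrected Fisher–Pearson `g1`; kurtosis is the
  excess `g2` (normal → 0); both use population moments;
- `cv` = population SD / mean;
- entropy is the base-2 Shannon entropy of a 16-bin histogram spanning
  the patch's own min–max range;
- degenerate (zero-variance) patches: `s = k = cv = e = 0` by
  convention; a zero *mean* with nonzero variance yields `cv = 0` with a
  warning counting the affected patches;
- the global `sigma` and `mad` are the population SD and the unscaled
  median absolute deviation.

The sweep has a vectorized fast path for full interior windows and a
scalar fallback for border-truncated ones; a naive double-loop reference
implementation in the test suite checks both paths to 10⁻¹⁰ relative on
random volumes (up to 20 × 20 × 3, 100 cases).

## Selection and classification

**Normalization.** Features are min–max scaled to [0, 1] and then
z-scored. "Normalize" and "standardize" name two different transforms and
we apply them in that order; the z-score uses the sample SD. Both
parameter sets are learned on training rows only and applied unchanged to
test rows. Constant training columns are dropped with a warning.

**LASSO.** L1-penalized logistic regression (`glmnet`) over 100
log-spaced λ down to 10⁻⁴·λ_max, λ chosen by the minimum mean
cross-validated binomial deviance over seeded stratified 10 folds;
nonzero coefficients at λ* are ranked by absolute value.

**Couple selection.** All unordered pairs of LASSO-selected features with
|Pearson ρ| < 0.15 on the training rows are candidates. Each member gets
a two-sided Wilcoxon rank-sum p-value (exact permutation when the smaller
group has ≤ 10 tie-free observations, otherwise the normal approximation
with tie and continuity corrections). A couple's p-value is the **max**
of its members' — both features must discriminate on their own; max is
the conservative combiner and gives each couple a single p-value, which
is what a count of "significant couples" presupposes. Holm–Bonferroni is
applied over the candidate couples and the significant couple with the
smallest p wins; ties break by larger summed |LASSO coefficient|, then
lexicographically.

**Training-set construction.** The 48/28 training/holdout split (18 + 30
vs 8 + 20 by class) keeps the patients *closest* to the separating
hyperplane of a preliminary class-weighted linear SVM (C = 1) fitted on
all standardized rows — the candidates for becoming support vectors. The
preliminary standardization necessarily uses all rows (no training set
exists yet); everything downstream re-learns its parameters on the
training rows only.

**SVM tuning.** Linear SVM on the selected couple. The kernel scale γ is
realized as input scaling `x/γ` (the standard meaning of a kernel-scale
hyperparameter); the misclassification cost of each class is C scaled by
that class's prior probability in the fitted data. Grids: C ∈ 10⁻²…10³
(13 log steps), γ ∈ 10⁻¹…10¹ (9 steps) — the C grid deliberately spans
the C < 1 boundary used by the filter below. Each of the (default 100)
repetitions of stratified 3-fold CV picks its best (C, γ) by mean
held-out F2 (β = 2: recall weighted four times precision, matching the
clinical cost of missing significant cancer); F2 ties — frequent on
16-patient folds — break by held-out AUC, then by the smallest cost at or
above 1, then smallest γ. The repetition's best is refit on the full
training set and a binomial-logit (Platt-style) calibration is fitted to
its training decision values.

**Filter cascade.** Candidates are dropped if (1) validation AUC exceeds
training AUC (overfitting signature), (2) C < 1, (3) training F2 < 0.80.
The survivor with the highest validation F2 is the final model (ties:
higher training F2, then smaller C). The calibrated probability is the
radiomic score.

**Evaluation.** Empirical ROC with "positive if score ≥ t"; AUC via the
rank (Mann–Whitney) identity so ties count one half; 95% CI by stratified
percentile bootstrap with 2000 resamples (the CI construction is
otherwise unspecified in this literature; the bootstrap is
assumption-light and seedable). The operating point is the Youden cutoff
(max SE + SP − 1), ties resolved toward higher specificity — the less
overtreatment-prone operating point. Metrics with zero denominators are
reported as explicit `NA`s with an `undefined` flag, never silent zeros.

**Reproducibility.** One master seed is fanned out to per-stage seeds
(cohort, LASSO folds, CV repetitions, bootstrap) by consecutive draws
from a generator seeded with it; identical configurations reproduce
identical artifacts bit for bit. `run_pipeline()` writes every
intermediate (manifest, features CSV, selection, model and report JSONs,
provenance log) so each reported number is traceable.

## The synthetic phantom cohort

Real patient volumes for this task are not publicly available, so the
generator builds the *statistical* situation the analysis assumes, not
realistic anatomy:

- geometry: isotropic in-plane spacing (default 1.5 mm, the middle of
  the 1.41–1.67 mm acquisition range), 3 mm slices, one elliptical
  lesion per patient spanning 3–6 slices with per-slice ellipse semi-axes
  drawn from 4–9 mm and shrinking toward the lesion's first/last slice;
- background: i.i.d. Gaussian signal (mean 100, SD 10, arbitrary
  units); lesion baseline mean 160 (hyperintense, as on high b-value
  DWI) with voxel noise SD 15;
- **heterogeneity** (significant class only): a smooth zero-mean
  Gaussian random field added to the lesion mean, unit-variance by
  construction (white noise convolved with a unit-L2 Gaussian kernel) and
  scaled to SD `heterogeneity_effect`; the kernel gives a ~5 mm
  correlation length so the heterogeneity survives patch averaging at the
  ~1 cm patch scale;
- **asymmetry** (significant class only): the lesion noise becomes a
  shifted log-normal matched to mean 0, SD `noise_sd` and skewness
  `asymmetry_effect` — a single-parameter control of right-skewness.

Default effects are `heterogeneity_effect = 15` and `asymmetry_effect =
1.2`. This sizing is deliberate and worth explaining. Because the two
planted effects vary independently across patients, any two features that
each separate the classes strongly acquire a *class-induced* pooled
Pearson correlation of roughly `pq·d₁d₂ / √((pq·d₁²+1)(pq·d₂²+1))` (d =
standardized class separation, pq the label variance). With the 0.15
correlation ceiling this means two features with d ≥ ~0.9 each can never
form a candidate couple unless their within-class correlations happen to
cancel the class-induced part. Much stronger effects therefore make the
selection stage abort on most cohorts (every discriminant couple is
"correlated"), while much weaker ones fail the Holm correction. The
defaults sit in the band where the published workflow is feasible:
selection succeeds on most seeds and the holdout AUC is high. A
corollary, verified by the recovery simulations in the test suite, is
that the selected couple is usually a *conjugate* pair — e.g. a
dispersion summary of the local kurtosis with a tail summary of the local
coefficient of variation — whose negative within-class correlation
offsets the class-induced part, rather than the nominally planted
`(m_sigma, s_M90th)` pair itself. Several near-equivalent features read
each planted contrast (`m_sigma`/`m_iqr`/`m_mad` for heterogeneity;
`s_mean`/`s_M90th`/`k_*` for asymmetry, since a skewness-1.2 log-normal
also carries excess kurtosis ≈ 2.4), and the procedure cannot, and need
not, tell them apart.

What the phantom does **not** emulate: MR physics (no Rician noise,
bias fields, T2 shine-through or motion), anatomy (no zonal structure,
no realistic lesion shapes), multifocality (one lesion per patient;
multi-lesion patients are handled only through the extractor's pooling
rule), or scanner heterogeneity. Passing recovery tests therefore shows
that the *pipeline machinery* is faithful — that planted class contrasts
of the intended kind are found, classified and evaluated correctly — not
that comparable performance would be obtained on patient data.

## Problem sizes used by the tests

The test suite mirrors the study dimensions where they matter (76 = 26 +
50 patients, 48/28 split, 3 folds of 6 + 10) and scales simulation
volumes to keep the suite fast: recovery runs use 20 cohorts with 10 CV
repetitions instead of 100 (the repetition count affects only how many
candidate models the filter cascade sees), oracle checks use 100 random
instances per operation, and the Wilcoxon null calibration uses 10,000
simulations at n = 20 + 20. The acceptance script runs the full 100
repetitions.

## Known limitations

- The correlation-ceiling arithmetic above makes recovery of one
  *specific* feature couple fundamentally unidentifiable whenever several
  features read the same planted contrast; only the contrast families are
  recoverable.
- With generous effects the calibrated scores saturate (medians near 0
  and 1, CIs collapsing to [1, 1]); the phantom demonstrates correctness,
  not realistic score spread.
- The preliminary SV-candidate split ranks patients with a single
  class-weighted linear SVM at C = 1; the published description of that
  construction is terse and other margin-based orderings are plausible.
- `cv`-type features are unstable when patch means approach zero; on
  positive MR magnitude images this does not arise, and the extractor
  warns if it ever does.
- Exact Wilcoxon p-values are only used for small tie-free groups; at
  the study's group sizes the tie-corrected normal approximation is used
  throughout, whose null calibration the test suite verifies empirically.
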