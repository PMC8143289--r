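# locrad — local first-order radiomics for prostate lesion classification

`locrad` implements a complete radiomic analysis for predicting clinically
significant prostate cancer (csPCa, biopsy Gleason score ≥ 3+4) versus
non-significant cancer (ncsPCa, Gleason 3+3) from lesion regions of
interest drawn on high b-value diffusion-weighted MR volumes (or on the
coregistered ADC maps, which share the DWI geometry).

The method, end to end:

1. **Local first-order features.** For every ROI pixel, seven first-order
   statistics — mean *m*, median *M*, skewness *s*, excess kurtosis *k*,
   interquartile range *iqr*, coefficient of variation *cv* and Shannon
   entropy *e* — are computed over a square in-slice patch centred on the
   pixel. The patch side follows the pixel spacing, `side = 2⌊5 mm /
   spacing⌋ + 1` (5–7 pixels at typical prostate DWI resolutions), so each
   patch explores roughly 1 cm² of tissue. Each of the seven per-pixel
   distributions, pooled over all lesion slices of a patient, is then
   summarized by twelve global statistics (the seven above plus maximum,
   standard deviation σ, median absolute deviation, and the mean and
   median of the last decile), giving an 84-feature vector per patient
   with names like `m_sigma` (σ of the local means) and `s_M90th` (median
   of the last decile of the local skewness).
2. **Feature-couple selection.** Features are min–max scaled and
   z-scored with parameters learned on the training rows, ranked by LASSO
   logistic regression (λ by 10-fold CV, minimum-deviance rule), screened
   to pairs with |Pearson ρ| < 0.15, and the couple with the smallest
   Holm–Bonferroni-corrected Wilcoxon rank-sum p-value is kept.
3. **SVM workflow.** The training set is built from the support-vector
   candidates of a preliminary class-weighted linear SVM (patients closest
   to the separating hyperplane). A linear SVM with kernel scale γ and
   class-prior-weighted cost C is tuned by 100× repeated stratified 3-fold
   CV on the F2-score, candidates are filtered (validation AUC must not
   exceed training AUC; C ≥ 1; training F2 ≥ 0.80), and the survivor's
   decision values are mapped through a binomial-logit calibration to a
   radiomic probability score.
4. **Evaluation.** ROC/AUC with stratified bootstrap 95% CIs;
   sensitivity, specificity, informedness I = SE + SP − 1, PPV, FDR and
   F2 = 5·PPV·SE/(4·PPV + SE) at the Youden cutoff; waterfall and
   group-separation (boxplot) data.

Patient imaging data of the original study are not publicly available, so
the package ships a synthetic phantom-cohort generator
(`generate_cohort()`) that plants the two class contrasts the analysis is
designed to read — heterogeneity of the local lesion mean (a smooth random
mean field) and asymmetry of the lesion intensity distribution
(right-skewed noise) — in NIfTI volumes with realistic acquisition
geometry. Every stage of the pipeline is exercised and tested against
this generator.

## Worked example

```r
library(locrad)

cfg <- run_config(cohort = cohort_config(n_ncs = 26, n_cs = 50),
                  n_reps = 10, n_boot = 500, seed = 42,
                  out_dir = file.path(tempdir(), "demo"))
res <- run_pipeline(cfg)
print(res$selection)
print(res$model)
print(res$report_test)
```

```
selection_result: 12 LASSO features, 20 uncorrelated couples, 4 significant
selected couple: k_mad + cv_M90th (p = 8.14e-06)
locrad_model: couple k_mad + cv_M90th, C = 1.21, gamma = 1.78
  train AUC 0.989 / F2 0.974; validation AUC 0.989 / F2 0.987
locrad_report: n = 28, AUC = 1.00 (95% CI 1.00-1.00)
  at Youden cutoff 1.000: SE 1.00, SP 1.00, I 1.00, PPV 1.00, FDR 0.00, F2 1.00
  score medians: ncs 0.01, cs 1.00 (separation p = 6.4e-07)
```

The 76-patient phantom cohort (26 ncsPCa + 50 csPCa) is split into 48
training and 28 holdout patients; LASSO retains 12 features, the
correlation filter leaves 20 candidate couples of which 4 survive the
Holm-corrected Wilcoxon test, and the selected couple — a dispersion
measure of the local kurtosis paired with a tail summary of the local
coefficient of variation, both readouts of the planted heterogeneity and
asymmetry — classifies the 28 holdout patients perfectly (the phantom
effects are deliberately generous; the radiomic score medians of 0.01
versus 1.00 show the two groups pushed to the calibration extremes).
Every intermediate artifact (cohort NIfTIs + manifest, feature CSV,
selection/model/report JSONs, provenance log) is written to `out_dir`.

`run_pipeline()` on a zero-effect cohort
(`cohort_config(heterogeneity_effect = 0, asymmetry_effect = 0)`) ends
either in a no-significant-couple null result or a chance-level holdout
AUC — a useful negative control.

## Package layout

- `R/synthetic_cohort.R` — phantom cohort generator (NIfTI + manifest)
- `R/io.R` — volumes, masks, feature tables, model/report JSON
- `R/local_radiomics.R` — patch sweep and the 84-feature extractor
- `R/feature_selection.R` — normalization, LASSO, ρ filter, Wilcoxon/Holm
- `R/svm_workflow.R` — SV-candidate split, repeated-CV tuning, filters, score
- `R/evaluation.R` — ROC/AUC/CI, Youden metrics, reports and plots
- `R/pipeline.R` — one-call orchestration with seed fan-out
- `vignettes/locrad-methods.Rmd` — model, assumptions, design choices
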