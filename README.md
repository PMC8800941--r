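# petrad

Co-clinical FDG-PET radiomics in R: robust feature screening and compact
radiomic signatures of therapy response.

## The problem

In co-clinical oncology trials, a preclinical arm of patient-derived tumor
xenografts (PDX) runs alongside a clinical trial in the matched cancer
subtype (here: triple-negative breast cancer under neoadjuvant
docetaxel/carboplatin). FDG-PET is acquired in both arms, and the question
is whether quantitative image features — beyond the standard SUV metrics —
can *predict* response to therapy from baseline scans and *assess* it from
the change between on-treatment and baseline scans. Because radiomic
features are numerous, mutually redundant, noisy, and often mere surrogates
of tumor volume, they must be triaged before any of them is allowed into a
classifier.

`petrad` implements that workflow end to end for users who have 3D SUV (or
raw activity) volumes with aligned binary tumor masks:

1. **Quantitation** — voxelwise SUV normalization
   `SUV = activity (Bq/mL) × weight (g) / dose (Bq)`, the SUV/SUL panel
   (SUV_mean, SUV_max, SUV_peak over a ~1 mL sphere, lean-body-mass scaled
   SUL_peak per PERCIST, TLG, …), caliper volumes `V = 1/6·L·W²`, metabolic
   tumor volume, and the ±20% caliper-volume trichotomy of preclinical
   response.
2. **Feature panel** — a fixed 131-feature manifest: 37 first-order
   intensity/histogram features on the raw grid, 83 texture features
   (GLCM 25, GLRLM 16, GLSZM 16, GLDZM 16, NGTDM 5, GLDM 5) after isotropic
   resampling and equal-probability quantization to N_g = 64 gray levels,
   plus tumor volume, MTV, and 9 SUV metrics.
3. **Robustness screen** — test–retest reproducibility via Lin's
   concordance correlation (pass at LCC ≥ 0.7), redundancy pruning at
   Spearman ρ ≥ 0.9 with P < 0.001 (the higher-LCC member of each pair is
   kept) with hierarchical clustering of the correlation heatmap, and
   tumor-volume dependency (Spearman flag; linear/log/power/exponential
   fits selected by minimum AIC). The robust set is the intersection.
4. **Signature + models** — ReliefF relevance ranking (k = 10, full pass,
   relevance threshold τ = 0.05), 4-feature radiomic signatures ("RadSig")
   per task, and stratified 10-fold cross-validation of CART (Gini), RBF
   SVM, and Gaussian naive Bayes, reported as accuracy, F-score,
   sensitivity, specificity, precision, and NPV from a pooled confusion
   matrix — benchmarked against SUV_mean, SUV_max, and SUL_peak.

Because no public imaging cohort ships with the package, a digital phantom
module (`phantom_config()`, `generate_scan()`,
`generate_test_retest_pair()`, `generate_longitudinal_cohort()`) simulates
textured ellipsoidal tumors with known ground truth at preclinical
(~0.8 mm) and clinical (~2 mm) voxel sizes, so the whole pipeline is
testable offline. The clinical interim-analysis lesion table (25 lesions,
20 patients, 10 with pathological complete response) is packaged and its
group statistics recompute exactly.

## Worked example

```r
library(petrad)

cfg <- phantom_config(n_subjects = 12, tumor_radius_range_mm = c(3, 4.5),
                      effect_size = 2, seed = 5)
res <- run_pipeline(cfg, n_retest = 8, folds = 6)

res$screen
#> <robustness_report> 129 features screened
#>   reproducible (LCC pass): 116
#>   redundancy-dropped:      93
#>   volume-flagged:          2
#>   clusters:                8
#>   robust set:              29

res$prediction$radsig
#> <radsig> task = prediction
#>   1. fo.mad                       w = 0.3883
#>   2. ih.min                       w = 0.2822
#>   3. ih.range                     w = 0.2822
#>   4. fo.p90                       w = 0.2263

round(res$prediction$performance$nb$metrics, 1)
#>    accuracy     f_score sensitivity specificity   precision         npv
#>        91.7        88.6        88.9        96.3        91.7        96.7
```

Of the 129 screened features (the panel minus the two volumes), 116
reproduce across the simulated test–retest pairs, the redundancy prune
removes 93 mutually correlated ones, and 2 track tumor volume; 29 robust
features remain. ReliefF then ranks dispersion features (mean absolute
deviation, histogram range, …) on top — exactly the heterogeneity signal
the phantom plants in responders — and the 4-feature naive Bayes signature
classifies the three response classes at 91.7% pooled cross-validated
accuracy, versus 50% for an SUV_mean-only model (an 83% relative
improvement, `res$prediction$comparison$improvement`).

The same flow over larger simulated cohorts, with all tables and figures
written under `results/`, is scripted in `analysis/01_simulate.R` through
`analysis/06_clinical_cohort.R` (run them in order from the repository
root).

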