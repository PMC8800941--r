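---
title: "Co-clinical FDG-PET radiomics: models, screens, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-clinical FDG-PET radiomics: models, screens, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrad)
```

`petrad` turns 3D PET volumes with binary tumor masks into a screened,
compact radiomic signature of therapy response. This vignette explains the
quantitative models behind each stage, the tunable parameters and their
defaults, what the synthetic phantom does and does not emulate, and the
design decisions taken where the methodology is genuinely open.

## Quantitation

Voxel activity (Bq/mL) is normalized to the standardized uptake value

$$\mathrm{SUV} = \frac{\text{activity} \times \text{body weight (g)}}{\text{injected dose (Bq)}},$$

a linear, order-preserving transform, so every rank-based statistic is
identical on activity and SUV grids. The SUV panel comprises nine metrics:
SUV_mean, SUV_max, SUV_peak, SUL_peak, SUL_mean, SUV_min, SUV_sd,
SUV_median, and TLG. SUV_peak is the largest mean over a sphere of fixed
volume (1 mL by default) realized on the voxel grid and centered at each
in-mask voxel; ties go to the first voxel in column-major order, and a VOI
smaller than the sphere falls back to the whole-VOI mean with an explicit
flag (routine for mouse tumors, which are usually below 1 mL). SUL scales
SUV by lean body mass over total mass; the Janmahasatian equations supply
LBM for clinical subjects, while preclinical SUL is defined equal to SUV
because lean-body-mass formulas do not apply to mice. The sphere averages
over all voxels (also outside the mask, per PERCIST practice), with voxels
outside the field of view contributing zero.

Metabolic tumor volume thresholds at 40% of SUV_max by default — the
threshold is configurable because no single convention dominates — and
TLG = SUV_mean × MTV. Caliper volume is implemented literally as
$V = \tfrac16 L W^2$, the convention used in the PDX therapy protocol; the
$\pi/6$ ellipsoid variant is available behind a flag because both forms
circulate in the preclinical literature. Preclinical response is the
caliper-volume trichotomy: more than 20% shrinkage is response, more than
20% growth is no response, and the closed interval in between is partial
response, so every finite input receives exactly one label.

## The 131-feature panel

The manifest (`feature_manifest()`) fixes 131 named features: 37
first-order, 83 texture, tumor volume, MTV, and the nine SUV metrics — 120
of them "radiomic" (first-order + texture). The exact composition of the
texture block (GLCM 25, GLRLM 16, GLSZM 16, GLDZM 16, NGTDM 5, GLDM 5) is
a package design decision: the constraint set honored exactly is the
total of 131, the 37 first-order features, and quantization at
$N_g = 64$; the manifest carries a version string so the composition is
swappable without silent drift.

First-order features are computed on the raw SUV grid over in-mask voxels
only — no resampling — as 18 intensity statistics (population moments;
kurtosis is excess kurtosis) plus 19 statistics of the equal-probability
histogram. Texture features are computed on the other branch: trilinear
isotropic resampling (nearest-neighbour for the mask, target = the scan's
smallest native spacing by default, so already-isotropic phantoms pass
through unchanged), then equal-probability quantization: in-mask
intensities are mapped through their empirical CDF into $N_g$ levels, so
level occupancies are as uniform as ties permit and the mapping is
monotone. A consequence verified by test: every higher-order feature is
invariant to any strictly monotone intensity transform.

Co-occurrence and run-length matrices use the 13 unique 3D directions at
distance 1; matrices are symmetrized and normalized per direction, features
computed per direction, and the 13 values averaged (the "averaged"
aggregation scheme). Zone families use 26-connected components;
the distance-zone family attributes each zone its minimum city-block
distance to the mask border, border voxels having distance 1. Degenerate
inputs are defined rather than left to produce NaN: a constant region has
GLCM correlation 1, information correlation 1 equal to 0, and zero
entropies. Each texture family is validated feature-by-feature against an
independent brute-force implementation (explicit loops over voxel pairs,
run walks, flood-filled zones, and neighbourhoods) on small random grids,
including grids with holes in the mask.

## Robustness screening

Three screens run in the order reproducibility → redundancy → volume, and
the robust set is their intersection. (The order in which the first two are
applied does not change the intersection; it only changes which screen gets
"credit" for a doubly-bad feature.) Both volumes (`tumor_volume`, `mtv`)
are excluded from screening, leaving 129 candidates of the 131.

*Reproducibility.* Lin's concordance correlation
$\mathrm{LCC} = 2\,\mathrm{cov}(x,y) / (\sigma_x^2 + \sigma_y^2 + (\bar x - \bar y)^2)$
(population moments) over paired day-1/day-2 feature values; a feature
passes at LCC ≥ 0.7. Unlike Pearson correlation, LCC penalizes location and
scale shifts, and $|\mathrm{LCC}| \le |r|$ always.

*Redundancy.* Spearman correlation between features with the large-sample
t approximation for P values; pairs with ρ ≥ 0.9 and P < 0.001 are
redundant. The prune is greedy: the involved feature with the lowest
test–retest LCC is dropped first (ties resolved toward the later feature in
manifest order). Reproducibility arbitrates because it is the screen's own
first criterion; with distinct LCCs the result is order-insensitive, which
is enforced by a property test. Average-linkage hierarchical clustering on
distance $1 - |\rho|$ (cut at 0.5 by default) reports the cluster structure
of the correlation heatmap; linkage, distance, and cut are conventional
heatmap practice and all configurable.

*Volume dependency.* Each feature is regressed on tumor volume under four
candidate forms — $a+bV$, $a+b\log V$, $aV^b$, $ae^{bV}$ — by least squares
(the nonlinear forms via Levenberg–Marquardt with log-linear starting
values). Model choice is minimum AIC under Gaussian residuals with
$k$ = parameters + 1; BIC is reported and disagreement flagged. Residual
sums of squares are floored at a scale-relative tolerance
($10^{-12}\,\overline{f^2}$) so that on noiseless data two forms that both
fit exactly tie and the earlier (simpler) candidate wins — without the
floor, log-likelihoods of near-zero residuals are numerically unbounded
and the winner would be decided by rounding error. The *flag* for volume
coupling deliberately uses the raw Spearman ρ > 0.9 with P < 0.001, not
the fitted model's goodness of fit: the fit explains the form of a
dependency, the correlation decides whether one exists. No multiplicity
correction is applied to the P < 0.001 screen (a raw threshold is the
stated convention).

## ReliefF and the radiomic signature

ReliefF scores each feature by its ability to separate nearest neighbours
of different classes: for each instance, the k = 10 nearest same-class hits
and, per other class, the k nearest misses (Manhattan distance on min–max
scaled features) contribute prior-weighted miss differences minus hit
differences. The package uses a deterministic full pass over all instances
rather than random subsampling — with cohorts of 20–60 scans the full pass
is cheap and removes Monte-Carlo noise, making weights exactly
permutation-invariant (tested). Multi-class problems (the preclinical
trichotomy) use the Kononenko prior-weighted extension. Weights lie in
[−1, 1]; features with weight above τ = 0.05 (an absolute-weight reading
of the relevance threshold) form the shortlist, capped at 15, and the top
4 constitute the signature per task. The prediction task uses baseline
features; the assessment task uses on-treatment minus baseline differences.
Weights are validated against an exhaustive brute-force ReliefF on ≤ 30
instances.

## Classifiers and evaluation

CART (rpart, Gini splits, binary partitions, effectively unlimited depth:
cp = 0, minsplit = 4 — defaults suited to n ≈ 20–60 cohorts), RBF-kernel
SVM (e1071, L2 regularization with cost C = 1 and
γ = 1/(d·Var(X)) by default; no inner tuning loop, since none is part of
the protocol), and Gaussian naive Bayes. The NB implementation is the
package's own small Gaussian model because its variance-smoothing
convention (adding $10^{-9}\times$ the largest feature variance to every
class-conditional variance) is an explicit, controlled stabilizer for
near-constant features within folds.

Evaluation is stratified 10-fold cross-validation: folds are dealt
round-robin within class by a seeded shuffle (optionally by patient group,
so lesions of one patient never straddle train and test), features are
standardized with training-fold statistics only, and the out-of-fold
predictions are pooled into a single confusion matrix from which accuracy,
F-score, sensitivity, specificity, precision, and NPV are computed (in
percent). Pooling, rather than averaging per-fold metrics, keeps the
estimates stable at n ≈ 20–30 where folds hold only 2–3 scans. Multi-class
metrics are macro-averaged one-vs-rest; accuracy stays overall. Signature
performance is compared against single-feature SUV_mean / SUV_max /
SUL_peak models trained with the same folds; improvement is
100(RadSig − SUV)/SUV per metric.

## The phantom: what it emulates, and what it does not

The generator renders one ellipsoidal tumor per subject on a noisy
background grid. Interior texture is a correlated Gaussian random field:
white noise smoothed by a Gaussian kernel whose σ is the texture
correlation length, normalized to unit variance, scaled by
`texture_amplitude` × tumor mean. This gives a single knob that moves the
higher-order features. Voxel noise is added on top and intensities are
clipped at zero (SUV is nonnegative). Arms differ only in voxel spacing
(0.8 vs 2.0 mm), tumor size range (4–7 vs 12–22 mm semi-axes), correlation
length, and dose/weight metadata scale — mirroring the harmonized
processing of the two arms. Scans are generated in activity units with
dose and weight drawn per scan (6.66–8.14 MBq and 20–28 g preclinical;
~370 MBq and 55–90 kg clinical), so SUV normalization is exercised
end-to-end.

Test–retest pairs re-render the same tumor with three perturbations scaled
by `retest_jitter`: the texture field is blended with a fresh realization,
the tumor center shifts sub-voxel, and voxel noise is redrawn — the
intensity and boundary failure modes of repeatability. Jitter 0 reproduces
day 1 bit-exactly, and mean LCC across the panel is non-increasing in
noise (tested over a seed ensemble). The longitudinal cohort assigns
latent classes (`round(responder_fraction × n)` responders, the rest split
between partial and no response), draws an endpoint volume change in the
class's interval (−60..−25 / ±15 / +25..+60 %), and scales the axes
accordingly, so the caliper trichotomy recovers the latent label by
construction. `effect_size` controls the planted baseline-heterogeneity
difference of responders (and its on-treatment decline); at 0 the baseline
images are exchangeable across classes and classifiers sit at chance.

Simulation defaults are the study conditions used throughout: 40
test–retest pairs, a 30-subject therapy cohort with responder fraction
0.5, background SUV 0.5, tumor SUV 3, texture amplitude 0.4, noise SD 0.1,
jitter 0.05, effect size 2. Tumor morphology statistics of real PDX are
not published with the protocol, so phantom realism is calibrated only to
voxel size and qualitative heterogeneity. What passing tests on phantoms
show is that the *machinery* is correct — matrices count what they claim,
screens flag what they are defined to flag, planted signal is recovered;
they do not show that any particular feature predicts response in real
tumors, and the cohort-dependent counts of the original study (such as
94/129 reproducible or 62 optimal features) are reproduced only
qualitatively. There is no PET physics in the phantom: no sinograms,
scatter, attenuation, or reconstruction artifacts, and no MR.

For the selection and model stages there is also a feature-space phantom
(`simulate_feature_table()`) that plants exactly `n_signal` discriminative
columns among Gaussian decoys; it drives the recovery and saturation
checks (with 4 planted features, ReliefF ranks all 4 on top and the
accuracy-versus-feature-count curve saturates near 4).

## Numerical choices and edge cases

- Equal-probability quantization maps a constant region to a single level;
  histograms with one occupied bin have entropy 0 and uniformity 1.
- GLCM on a single-voxel mask errors (no pairs); inside `extract_features()`
  family failures degrade to NA with a hard error only past 10% of the
  panel.
- Lin's CCC on two constant vectors is undefined and returns NA with a
  warning.
- Spearman P values use the t approximation; |ρ| = 1 is assigned P = 0.
- Fold assignment, phantom rendering, and ReliefF are pure functions of
  their seeds; reruns are bit-identical (tested).
- Problem sizes in the shipped tests and acceptance script (6–40 retest
  pairs, 10–30 subjects, 3–4.5 mm test tumors) were chosen as the smallest
  cohorts at which the screens and recovery properties are stable.

## Known limitations

No wavelet or filtered feature maps, no shape features beyond volume, no
partial-volume correction, no kinetic modeling, and no external validation
cohort — the benchmark compares predictors within one (synthetic or
user-supplied) cohort. Orientation matrices of NIfTI inputs are ignored
(spacing only); masks and images must already be aligned on the same grid.
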