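---
title: "Methods: semi-automatic texture analysis of DCE-MRI lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic texture analysis of DCE-MRI lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`texomri` implements a two-dimensional radiomics workflow for dynamic
contrast-enhanced breast MRI. Each patient contributes one axial slice in
three phases — pre-contrast, post-contrast, and their pixel-wise
difference (the subtraction image, which highlights contrast uptake) —
plus an operator-drawn seed region of interest (ROI) around the lesion
and a binary reference label (FISH-positive / FISH-negative HER2 2+
status). The pipeline is:

1. **Segmentation** on the subtraction image: Otsu thresholding of the
   ROI pixels, erosion, extraction of the largest eight-connected
   component, dilation, and clipping to the ROI. The resulting contour
   is reused on the co-registered pre- and post-contrast slices.
2. **Normalization**: masked intensities are clipped to $\mu \pm
   3\sigma$ (computed over the masked pixels of the phase at hand) and
   quantized to 8 bits by flooring, the top edge mapping to level 255.
3. **Texture extraction**: 488 features per phase — 4 histogram moments,
   380 gray level co-occurrence matrix (GLCM) statistics (19 features
   $\times$ 4 distances $\times$ (4 directions + directional mean)),
   44 gray level run-length matrix (GRLM) statistics (11 features
   $\times$ 4 directions), and 60 discrete wavelet transform (DWT)
   subband descriptors (5 per level $\times$ 4 levels $\times$ 3
   wavelets: Haar, Daubechies-2, Symlet-4).
4. **Screening**: per feature, a Lilliefors-corrected Kolmogorov-Smirnov
   normality gate per group chooses between a pooled-variance Student t
   test and a two-sided Mann-Whitney U test; features with $P < 0.05$
   are retained. No multiplicity correction is applied by default — the
   screen is intentionally a raw univariate filter; `p.adjust` can be
   applied to the recorded p-values.
5. **Selection**: L1-penalized logistic regression (glmnet path of 100
   penalties spanning four decades), penalty chosen by 10-fold
   cross-validated deviance (minimum rule; a one-standard-error rule is
   available).
6. **Classification**: leave-one-out cross-validation of unpenalized
   logistic regression (LRA), ridge-stabilized quadratic discriminant
   analysis (QDA), and a support vector machine (SVM, RBF kernel,
   $C = 1$, $\gamma = 1/(p \cdot \widehat{\mathrm{var}}(X))$).
7. **Evaluation**: empirical ROC curves; AUC (tie-corrected
   Mann-Whitney statistic); DeLong structural-components variance;
   an approximate binomial-exact 95% CI; Youden-index operating points;
   paired z-tests between correlated AUCs from the DeLong covariance.

# Design choices on genuinely open points

Several procedural details are not determined by the workflow
description the package follows; they are pinned here as explicit,
configurable defaults.

* **Binarization polarity.** Foreground is *at or above* the Otsu
  threshold: enhancing lesions are bright on subtraction images.
* **Structuring element.** Disk of radius 2 for both erosion and
  dilation (configurable, disk/square). The mask is intersected with
  the ROI after dilation so the segmentation cannot leak outside the
  operator's region.
* **Otsu histogram.** 256 equal-width bins over the observed ROI range;
  candidate thresholds are interior bin edges, ties resolved toward the
  lowest qualifying threshold.
* **Per-phase normalization.** $\mu$ and $\sigma$ are computed on the
  phase being analyzed, so each phase is normalized independently.
* **GLCM.** Offsets $(0,d)$, $(-d,d)$, $(-d,0)$, $(-d,-d)$ for
  $d = 1..4$; matrices are symmetrized and normalized; 256 gray levels
  (matching the 8-bit quantization; optional rebinning exists because
  256-level matrices on small lesions are sparse). Feature names carry
  raw offsets (`"S(0,1) CON"`) because angle conventions are ambiguous
  across the literature. The 19 statistics are the classical Haralick
  set plus the extended dissimilarity/autocorrelation/cluster/
  normalized-inverse-difference family; entropies use the natural
  logarithm; the information measure of correlation is the first
  variant (IMC1). The directional mean per distance brings the family
  to $19 \times 4 \times 5 = 380$ values.
* **GRLM.** Runs are maximal same-level pixel sequences along a rake
  direction, truncated at mask boundaries; gray levels enter the
  low/high-gray emphases 1-based so level 0 remains finite.
* **DWT.** The mask's bounding box (outside-mask pixels filled with the
  masked mean) is padded to a multiple of $2^4$ and decomposed with
  periodic extension, which makes the transform exactly orthonormal
  (Parseval holds to machine precision; verified in the tests). Per
  level we emit normalized energies of the three detail subbands
  (codes HH = horizontal, DH = vertical, HD = diagonal), the
  approximation energy, and the approximation mean. Masks smaller than
  16 pixels in either direction reduce the depth with a warning and
  report the missing levels as `NA`; such features are recorded by the
  screen but never kept.
* **Normality gate.** The KS test is applied per group and *both*
  groups must pass for the t branch. The Lilliefors correction for
  estimated parameters uses the published Dallal-Wilkinson/Stephens
  approximations, implemented in-package (vectorization across 488
  features and LOOCV folds makes an external call-per-feature
  prohibitive) and cross-checked against `nortest::lillie.test` in the
  test suite.
* **Mann-Whitney.** Exact null distribution when $n_1 n_2 \le 400$ and
  no ties; otherwise normal approximation with tie and continuity
  corrections.
* **Contingency tests.** Pearson chi-square without continuity
  correction when all expected counts are $\ge 5$, else two-sided
  Fisher's exact test.
* **Selection-evaluation coupling.** Two modes. `paper` mode screens
  and selects once on the full cohort and cross-validates only the
  classifier — the classical sequential design, which is optimistic on
  null data (this optimism is itself asserted as a property test).
  `leakage_safe` mode re-runs screening and LASSO inside every LOOCV
  training fold; all calibration claims below use it.
* **Prior-corrected LOOCV scores.** Pooled leave-one-out scores suffer
  a stratification bias: the held-out patient's class is always the
  minority of its training fold, so prevalence-weighted scores are
  systematically depressed for the held-out class, biasing the null
  AUC well below 0.5. LRA scores therefore subtract the training-fold
  prior log-odds from the linear predictor and QDA uses equal class
  priors. A residual small-sample pessimism remains (null LOOCV AUC
  $\approx 0.45$ at $n \approx 50$); SVM margins are left uncorrected,
  which is why calibration checks use LRA.
* **Operating point.** Youden index ($\max$ sensitivity + specificity
  $- 1$), ties resolved toward higher specificity; samples score
  positive at or above the threshold.
* **Binomial exact CI for the AUC.** The AUC is treated as a
  proportion of concordant pairs with an effective pair count
  $n_\mathrm{eff} = \hat A (1-\hat A) / \widehat{\mathrm{var}}_\mathrm{DeLong}$
  and a Clopper-Pearson interval with continuous counts. This is an
  approximation of the construction used by common ROC software; its
  empirical 95% coverage over 500 simulated score cohorts ($n = 92$,
  true AUC 0.8) is measured in the acceptance tests and falls in
  [90%, 99%].

# The synthetic phantom

No imaging data ship with the package; the phantom module generates
cohorts with the statistical structure the analysis assumes, so every
stage is testable end-to-end.

Each case has one lesion — a disk with low-order radial modulation —
placed fully inside a 96 x 96 frame (radius 10-16 px). The pre-contrast
image is a flat background plus lesion contrast plus a stationary
correlated Gaussian random field (white noise smoothed with a Gaussian
kernel whose width is the field's correlation length) inside the lesion,
plus acquisition noise. Contrast uptake adds a second, class-conditional
correlated field (plus a mean enhancement of ~600 intensity units) to
the post-contrast image; the subtraction image recovers that uptake
field plus noise. The seed ROI emulates a hand-drawn region as the true
boundary dilated by 5 px.

The class effect is placed almost entirely in the *uptake* field
(correlation length 2.15 vs 1.55 px, field SD 140 vs 115, mean shift
38 vs 0 for positive vs negative), with only a token difference in the
pre-contrast field. Because the uptake field appears undiluted in the
subtraction image, diluted by shared pre-contrast texture in the
post-contrast image, and not at all pre-contrast, the class
separability ordering subtraction > post > pre emerges by
construction — the qualitative pattern the analysis is designed to
exhibit — with subtraction-phase SVM AUC above 0.8 under the defaults.
Per-patient biological heterogeneity (log-normal jitter of field SD and
correlation length, additive jitter of the mean shift, identical for
both classes) widens within-class spread so that AUCs sit in a
realistic 0.85-0.95 range rather than saturating at 1. These values
were fixed once as the generator's operating conditions.

What the phantom does *not* emulate: pharmacokinetic enhancement
curves, 3D lesion geometry and slice selection, spatially varying coil
sensitivity, rician noise, motion, or multi-lesion cases. Passing
calibration on the phantom therefore demonstrates the statistical
soundness of the pipeline, not clinical performance on real DCE-MRI.

# Problem sizes used by the test and acceptance runs

Simulation-based checks use deliberately scaled problem sizes chosen to
keep the suite fast while leaving the estimators meaningful: the
null-calibration study uses 20 cohorts of 92 patients (56 x 56 frames,
lesion radius 8-11) for the screening type-I rate, and 46-patient
subsets of the same cohorts for the leakage-safe null AUC; CI coverage
uses 500 simulated score cohorts of n = 92; the ordering check runs the
full default phantom (92 patients, 96 x 96) once; the effect-size
monotonicity property uses 40-patient cohorts at 64 x 64 over 3 effect
levels x 6 seeds.

# Numerical conventions and degenerate inputs

* Constant (zero-variance) ROIs quantize to the middle gray level and
  are flagged; their histogram skewness/kurtosis are defined as 0;
  constant GLCMs give COR = IMC = 0 by convention.
* A feature undefined for any patient (reduced wavelet depth) is
  recorded by the screen with `test_used = "none"` and never kept.
* Zero-variance samples are "maximally non-normal" (KS p = 0).
* Empty LASSO selections are explicit; downstream LOOCV then emits a
  constant non-informative score of 0.5 (AUC 0.5 by the tie
  convention) rather than a per-fold prevalence, which would
  anti-correlate with the held-out label.
* QDA covariances receive a ridge of $10^{-6} \cdot \mathrm{tr}(S)/p$;
  ties in Otsu's criterion and in the Youden scan resolve
  deterministically (lowest threshold; higher specificity).
* All randomness flows from a single seed (phantom sub-seed, LASSO fold
  assignment), making cohorts and reports byte-reproducible.

# Known limitations

* 2D only; no shape/size or filter-bank features.
* The GLCM feature count (380) follows the inventory's own arithmetic
  (19 named statistics, 4 distances, 4 directions + mean); descriptions
  that state "eighteen" features with the same total are reconciled in
  favor of the printed name list and total.
* The binomial-exact CI is an approximation (above), isolated in one
  function.
* `paper` mode reproduces the sequential screen-then-model design
  faithfully, including its optimism; use `leakage_safe` for unbiased
  performance estimates.
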