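---
title: "Methods: mammographic texture features and breast cancer risk scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mammographic texture features and breast cancer risk scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cirrus)
```

## The problem

Conventional mammographic density — the area of bright tissue above a
brightness threshold, absolute or as a percentage of the breast — is an
established breast cancer risk factor, but it summarizes a mammogram by a
single first-order quantity. This package implements an alternative: a
fully automated risk measure built from *second-order* texture statistics
of the craniocaudal (CC) view, which capture how gray levels co-occur
across space rather than how many pixels are bright. The pipeline runs from
raw image to an epidemiological risk gradient:

1. **Segmentation and QC** (`segment_breast()`, `quality_check()`): isolate
   the breast from background and labels; reject degenerate images.
2. **Texture features** (`quantize()`, `cooccurrence()`,
   `compute_features()`, `extract_features()`): 20 gray-level co-occurrence
   matrix (GLCM) features per mammogram, made resistant to digitizer
   differences.
3. **Aggregation** (`aggregate_median()`): one feature vector per woman,
   the featurewise median over all her mammograms.
4. **Risk score** (`bayes_lasso_fit()`, `bayes_lasso_score()`): Bayesian
   lasso logistic regression on standardized features; the score ("Cirrus"
   score) is the linear combination of posterior-mean coefficients and
   standardized features.
5. **Risk gradient** (`opera_adjust()`, `adjusted_or()`, `iqrr()`,
   `auc_from_log_or()`, `empirical_auc()`): odds ratio per age- and
   BMI-adjusted standard deviation, with closed-form interquartile risk
   ratio and AUC conversions.

A synthetic generator (`synthetic_config()`, `generate_image()`,
`generate_cohort()`) provides images and cohorts with the statistical
structure the pipeline assumes, so every stage is testable without patient
data.

## Segmentation and quality control

The breast is separated from background by a global intensity threshold,
after which foreground pixels are grouped into connected components; the
largest component is kept (bright labels and markers are detached
components and drop out), smoothed by morphological closing with a disc of
radius 5 px, and hole-filled. A valid mask must touch exactly one lateral
border (the chest-wall side) and cover 5–95% of the frame.

**Threshold choice.** The threshold is the 99.5th-percentile *order
statistic* of the top and bottom border bands (3 rows each), which are
background on a CC view because the breast enters the frame laterally. A
histogram-shape threshold such as Otsu's would be the more common default,
but it is not invariant to monotone intensity remappings: a gamma change
moves the variance-optimal split and can flip boundary pixels. An order
statistic commutes with any strictly increasing transform, so the mask —
and everything downstream — is *exactly* invariant to digitizer gain,
offset and curve differences. This exactness is tested, not just assumed.

Quality control rejects MLO views, images whose within-mask intensity range
is below `min_range_fraction` (default 0.05) of the nominal dynamic range,
and negative images (median background brighter than median breast). The
0.05 default is configurable; "abnormally low contrast" is inherently a
calibration choice, and on the generator's default images the pass rate is
required to be at least 97%.

## Digitizer-resistant GLCM features

Film digitizers differ in gain, offset and response curve. All texture
computation therefore starts from an **equal-mass (quantile) quantization**
of the masked intensities into `G = 64` gray levels: levels depend only on
intensity *ranks*, so any strictly monotone transform of the raw
intensities leaves the quantized image unchanged. Tied intensities always
share a level (ranks with ties taking the minimum), which keeps the map
deterministic.

The co-occurrence matrix counts ordered level pairs at the four offsets
(0, d), (d, 0), (d, d), (d, −d) with `d = 1`, each pair added with its
reverse, all four directions pooled into one matrix before normalization.
Pooling the symmetric direction set makes the matrix — hence every feature
— exactly invariant to 90°/180°/270° rotations and to horizontal/vertical
flips, which is the discrete form of the requirement that a mammogram yield
the same features irrespective of breast positioning. Only pairs with both
pixels inside the mask are counted, so features are also invariant to
translation of the masked content.

Twenty scalar features are computed from the normalized matrix
(autocorrelation, cluster prominence/shade, contrast, correlation,
difference entropy/variance, dissimilarity, energy, entropy, homogeneity,
two information correlations, maximum probability, two normalized inverse
differences, sum average/variance/entropy, variance). Where the literature
has competing variants, this package fixes: difference variance is the
variance of the absolute-difference distribution; sum variance is centered
on the sum average; homogeneity is the inverse difference moment
`sum p/(1+(i-j)^2)`; the two normalized inverse differences use the IDN/IDMN
normalizations by `G`; logarithms are natural with `0·log 0 := 0`. On a
constant (single-level) region, correlation-type features are undefined and
returned as `NA` sentinels; such images are QC-rejected in practice.

`G`, `d` and the direction handling are fixed package constants rather than
fitted quantities; `G = 64` keeps the matrix well-populated for breast-sized
masks at 256×256 and above. A scale property worth knowing: features are
comparable across image resolutions only when the offset distance scales
with resolution (d = 1 at 128 px corresponds to d = 2 at 256 px for the
same physical texture); at fixed d, resolution changes the physical
displacement being sampled and the features legitimately move.

## Per-woman aggregation

A woman's feature vector is the featurewise (marginal) median over all her
QC-passing mammograms — left and right, all visits pooled. The median is
permutation-invariant and robust to a single unusual mammogram; for an even
count it is the mean of the two central values; `NA` sentinels are excluded
per feature. A `single_earliest` mode (first visit only) supports
sensitivity analyses.

## Bayesian lasso logistic risk score

With 11 of the 20 features mutually correlated at |r| > 0.9, ordinary
maximum likelihood and stepwise selection are unstable: which of several
near-interchangeable features "wins" is essentially random. The package
therefore fits logistic regression with independent Laplace
(double-exponential) shrinkage priors on the standardized coefficients —
the Bayesian lasso — which spreads weight across correlated features
instead of arbitrarily selecting among them.

The model is explored by a Gibbs sampler with no tuning parameters:

* **Pólya-Gamma augmentation** of the logistic likelihood: latent
  `omega_i ~ PG(1, eta_i)` makes the conditional of the coefficients
  Gaussian. PG(1, z) is drawn exactly by Devroye's alternating-series
  method (implemented in C++, using R's RNG so `set.seed()` gives
  bit-identical chains).
* **Scale-mixture Laplace prior**: `beta_j | tau_j^2 ~ N(0, tau_j^2)` with
  exponential mixing; `1/tau_j^2` has an inverse-Gaussian conditional.
* **Sampled global penalty**: `lambda^2 ~ Gamma(1, 1)` a priori, updated
  from the local scales, so the regularization strength is estimated from
  the data rather than cross-validated.
* The intercept is unpenalized (flat prior). Defaults are 10,000 draws with
  the first 1,000 discarded as burn-in; a split-chain potential scale
  reduction above 1.1 on any coefficient raises a warning.

Features are standardized to zero mean and unit SD on the training sample
(cases and controls combined — the usual convention in penalized
regression), so posterior-mean coefficients are *standardized weights*. The
risk score for any woman is the inner product of those weights with her
training-standardized features; the intercept is omitted, making the score
relative (all-features-at-training-means scores 0). Missing features at
scoring time are imputed at the training mean with a warning; rows with
missing features are excluded from training.

## Risk-gradient statistics

**Adjustment.** Following the residual-based convention for comparing risk
measures (the OPERA approach), a measure is regressed on age and log BMI by
OLS *among controls only*; residuals for everyone are taken from that
control-fitted model and divided by the control-residual SD. Controls then
have mean 0 and SD 1 by construction, and the case mean equals the
standardized case-control separation. BMI enters all models as log BMI.

**OR per adjusted SD.** Logistic regression of status on the adjusted
measure plus age and log BMI (plus optional co-measures for joint models),
with Wald inference throughout: 95% CI multiplier 1.959964, two-sided Wald
p. Conventional density measures enter after Box–Cox-style transforms
(fourth root of absolute density, cube root of percent density) and the
same adjustment. When both conventional measures enter one joint model, no
collinearity pruning is applied.

**Closed forms.** For a normally distributed risk factor and a relatively
rare disease, the risk ratio between top and bottom quartiles is

`IQRR = Phi(log(OR) - b) / Phi(a - log(OR))`,  `a = Phi^{-1}(0.25) = -b`,

which the tests verify against a Monte-Carlo quartile-risk oracle to within
2% over OR 1.2–2.5. Under the equal-variance normal model the standardized
case-control mean difference equals log(OR) per SD, and
`AUC = Phi(log(OR)/sqrt(2))`, approximately linear in log(OR) over AUC
0.5–0.7. The empirical AUC is the Mann–Whitney statistic (midranks, ties
counted one half) with a Hanley–McNeil interval.

```{r iqrr}
iqrr(c(1.4, 1.76, 1.9))
auc_from_log_or(log(1.9))
```

## The synthetic generator

Textures are Gaussian random fields: white noise convolved (via FFT) with a
Gaussian kernel whose width is the woman's *correlation length*. Larger
widths give large, homogeneous patches; smaller widths give a scattered
pattern — the qualitative contrast between high- and low-risk texture the
pipeline is designed to detect. The field is masked to a half-ellipse
breast phantom attached to the left border (no pectoral muscle is
generated, matching the CC-only scope), with additive sensor noise, a
12-bit dynamic range, and an optional detached bright label rectangle.

Each woman's log correlation length is
`log(cl_control) + log(cl_case/cl_control)·case + covariate terms +
N(0, texture_effect_sd)`. With the defaults (4.0 vs 4.85 px, SD 0.3,
covariate slopes −0.05 on standardized age and log BMI), the planted
case-control separation is 0.64 latent SD — a true OR per adjusted SD of
about 1.9 for the latent parameter, the magnitude the pipeline is meant to
resolve. Setting equal correlation lengths gives a null configuration. Ages
are uniform on 40–70; BMI is lognormal(log 25.5, 0.15); the case fraction
defaults to 0.25; women carry 1–10 mammograms. A synthetic
conventional-density surrogate correlated with the latent parameter
(r = 0.45) is included for joint-model exercises.

**Feature-level mode.** Rendering and segmenting images is the slow path,
so `generate_cohort(mode = "feature")` draws per-mammogram feature vectors
directly from a linear-Gaussian emulation of the image pipeline: mean
response `mu0 + slope·(log width - log 4)` per feature, with the slopes,
intercepts and per-image noise SDs measured once by regressing
pipeline-extracted features on log width (8 replicates at each of 9 widths
log-spaced over 1.5–12 px, 256×256 phantoms, G = 64, d = 1). The per-image
noise has a two-block factor structure — the 11 smoothness-driven features
at pairwise |r| = 0.92 (signed by their direction of response), the other 9
at 0.8, cross-block 0.2 — mirroring the correlation pattern texture
features show in practice. At the per-mammogram level, features with low
signal-to-noise dilute observed pairwise correlations below the generating
values; after per-woman median aggregation the high-correlation block
structure re-emerges, and that is the level at which it is asserted.
`mode = "mixed"` renders a configurable fraction of women as images and
draws the rest at feature level with an interchangeable schema.

**What the generator does not emulate**: breast anatomy (ducts, vessels,
skin line), lesions, pectoral muscle, scanner artifacts beyond additive
noise and labels, and interval-versus-screen-detected case heterogeneity.
Passing tests on this generator demonstrates that the pipeline's
statistical machinery is correct and that a planted smoothness gradient of
realistic magnitude is recovered — not that the score is clinically valid
on real mammograms.

## Evaluation honesty

A score fitted and evaluated on the same women is optimistic: even under a
null configuration the learned direction correlates with in-sample case
status (ORs around 1.3–1.5 were observed at n = 700 with 20 features). The
package therefore separates the two semantics: `run_pipeline(eval =
"insample")` mirrors a combined-data fit evaluated on itself, while
`eval = "split"` fits on a seeded random half of the women and estimates
the OR and AUC on the held-out half; `cross_study_evaluate()` generalizes
this to train/test grids across named studies, where diagonal entries
measure in-sample optimism and off-diagonal entries external replication.
Null-configuration checks use held-out evaluation.

## Numerical choices and degenerate inputs

* Quantization requires at least `G` distinct masked intensities; constant
  images fail segmentation (no foreground) or QC (zero range).
* Co-occurrence requires at least one valid pixel pair; 0·log 0 = 0
  throughout; `info_correlation_2` clamps `1 - exp(-2(HXY2-HXY))` at 0
  before the square root.
* The Gibbs sampler guards `|beta_j|` below 1e-10 and caps the
  inverse-Gaussian mean at 1e8 when sampling local scales; the Cholesky of
  the (prior-regularized) precision is always well-defined, so exact
  collinearity and separation are handled without special cases.
* `opera_adjust()` refuses fewer than 10 complete control rows, a singular
  age/BMI design, and a zero control-residual SD; `adjusted_or()` treats
  non-convergence or |log OR| > 15 as separation and points to the
  Bayesian fit.
* Quantile/order-statistic computations use type-1 (inverse-ECDF)
  quantiles so that thresholds are observed values and commute with
  monotone transforms.

## Problem sizes used by the test suite

The shipped tests run the brute-force co-occurrence oracle on 200 random
images up to 16×16; feature invariance on 20 rendered 128 px phantoms;
sampler recovery at n = 2000, p = 20 with 2,500 draws; OR-recovery coverage
over 100 replicates at n = 3000; and the end-to-end planted-gradient run on
1,000 women (3% rendered as 256 px images) with 2,000 draws. These sizes
were chosen so the whole suite completes in a few minutes on one CPU while
keeping every assertion at its stated tolerance; the sampler's defaults
(10,000 draws / 1,000 burn-in) remain the recommendation for real analyses.

## Known limitations

* CC views only; MLO images are flagged at QC, and no pectoral-muscle
  removal is implemented.
* The segmentation background reference assumes the top and bottom image
  bands are background; unusual framing violating this needs a custom mask.
* The score is relative (no intercept), so it supports ranking and
  gradient estimation, not absolute risk calibration.
* Film-digitization artifacts beyond monotone intensity remappings (e.g.
  spatially varying gain) are outside the invariance guarantee.
* The feature-level generator is a linear-Gaussian emulation calibrated
  around widths 1.5–12 px; far outside that range it extrapolates.
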