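---
title: "Cell-cluster morphometry for liquid-based endometrial cytology: methods and design"
author: "cytocluster authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cluster morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions
behind `cytocluster`. The package analyzes low-magnification (4x
objective) fields of liquid-based endometrial cytology slides: it
binarizes each field, measures shape descriptors of every connected cell
cluster and the field's box-counting fractal dimension, averages over the
five fields captured per specimen, and runs the diagnostic (logistic,
ROC) and prognostic (cutpoint, Kaplan-Meier, Cox) statistics that
evaluate those features as markers for endometrial cancer (EC) and
atypical endometrial hyperplasia (AEH).

# Image preparation

**8-bit conversion.** RGB input is collapsed with Rec. 601 luminance
weights; higher bit depths are rescaled linearly to [0, 255] with
rounding half away from zero.

**Binarization.** The default automatic threshold is isodata (iterative
intermeans): the smallest integer threshold `t` satisfying
`t >= (mean(gray <= t) + mean(gray > t)) / 2`. We scan candidate
thresholds from below rather than iterating from the overall mean: the
intermeans map can have several fixed points, and when the foreground is
a small fraction of the image, iteration started at the global mean can
converge to a fixed point *inside* the background mode, splitting
background noise in half. The lowest fixed point sits between the modes
regardless of class imbalance, which is also the behavior of the classic
particle-analysis default. Otsu (between-class variance maximization over
all 256 thresholds) and a fixed threshold are available. Foreground
polarity is explicit; the default `dark_foreground` matches
Papanicolaou-stained clusters on a bright background. Two degenerate
cases return an all-background mask with a flag: a constant image, and an
effectively unimodal image whose two class means are closer than
`minContrast` (default 20 gray levels; real stained clusters separate
from background by > 100 levels). The computed threshold is always
logged in the field's provenance.

**Labeling.** Connected components via run-length union-find, 8-connected
by default (4-connected available), labels assigned in raster-scan order
of each component's first pixel. Components smaller than `minArea`
(default 64 px at 4x) are removed as debris; border-touching clusters are
kept. The defaults are package choices, surfaced in the configuration
and logged, since the upstream acquisition protocol does not fix them.

# Morphometry

**Boundary and perimeter.** Moore-neighbor tracing (clockwise,
deterministic topmost-then-leftmost start, Jacob's stopping criterion)
yields an 8-direction chain code; the perimeter weights axial steps 1 and
diagonal steps sqrt(2). Degenerate components fall back to their
unit-cell boundary (single pixel: 4; domino: 6), keeping circularity
finite. Two properties of this convention matter for interpretation:

* an axis-aligned `s x s` square measures exactly `4 (s - 1)`;
* a smooth boundary is *overestimated* by the digitization factor
  averaging `kappa = 8 (sqrt(2) - 1) / pi ~ 1.055` over orientations, so
  a large rasterized disk measures circularity near
  `1 / kappa^2 ~ 0.90`, not 1.0. Exact corner-corrected replication of
  any particular tool's perimeter is a non-goal; all comparisons within
  a study use one consistent convention, and the tests pin both
  properties (the square identity exactly, the disk against the analytic
  factor).

**Descriptors.** Circularity is `min(1, 4 pi A / P^2)`. Solidity is
pixel area over the shoelace area of the convex hull of the pixel-corner
point set (a convex digital shape therefore scores ~1, and a plus-sign of
five unit cells exactly 5/7). The fitted ellipse matches the component's
second central moments (with the 1/12 unit-square correction), rescaled
to the component's area; its angle is reported in degrees in [0, 180),
counterclockwise from the x axis. Feret diameters come from the hull:
the maximum is the largest vertex distance, the minimum the smallest
projection width over hull-edge directions (rotating calipers, which is
exact; a finite angle sweep is only an upper bound with linear kink
error).

**Fractal dimension.** `N(eps)` counts occupied boxes of an
origin-anchored grid for sizes {2, 3, 4, 6, 8, 12, 16, 32, 64} by
default (optionally minimized over several grid origins); the dimension
is minus the OLS slope of `log N` on `log eps`. It is computed once per
field on the binary mask of retained clusters — debris below `minArea`
is excluded just as it is from the descriptors — not per cluster
(per-cluster values are available but not part of the specimen summary).
On analytic fixtures at 243-512 px the estimator recovers 1 (line), 2
(filled square), log 8/log 3 (Sierpinski carpet; the triadic grid makes
the counts exactly 8^k), log 3/log 2 (Sierpinski triangle) and log 4/log
3 (Koch island boundary) within 0.05.

One empirical caveat the tests encode: for a *filled* region, boundary
roughness does not raise the measured slope — extra roughness adds
fine-scale boundary boxes but inflates the shape's large-scale spread
just as fast, so per-mask dimension is flat-to-decreasing in roughness.
What moves the field-level dimension is occupancy: how many clusters,
and how large. The synthetic generator therefore separates classes
through cluster count and size (which is also how occupancy drives box
counts on real binarized fields), while roughness drives circularity and
solidity.

**Aggregation.** Within a field, descriptors are averaged unweighted
over clusters (the angle as axial data, via the circular mean of doubled
angles; a plain mean is available); the cluster count and field fractal
dimension are attached. Within a specimen, field rows are averaged
unweighted over the (up to five) fields; descriptor means use only
fields with at least one cluster, the fractal dimension every field with
foreground, and specimens with fewer than five contributing fields are
flagged. Whether the upstream protocol averaged by mean, median or area
weighting is unknown; the unweighted mean is the declared convention.

# Diagnostic statistics

The positive class pools AEH with the carcinomas (AEH, EM G1-G3,
serous/clear-cell); the negative class is normal endometrium and
hyperplasia without atypia. Age is dichotomized at >= 55 years
(inclusive), cytology at positive-or-suspicious versus negative.

Logistic fits are maximum likelihood with Wald CIs on the log-odds scale
(profile likelihood was considered and rejected to keep the reported
intervals consistent with the Wald p-values; separation is detected and
reported as an infinite OR rather than a silently diverged fit). The ROC
uses every observed threshold with the `score >= t` rule; the AUC is the
Mann-Whitney statistic with ties counted 1/2, its variance the DeLong
placement-value estimate, and the reported cutoff maximizes the Youden
index with ties broken toward higher specificity. Combined
cytology-plus-feature scores are fitted probabilities of the
two-predictor logistic model, fitted and evaluated in sample (no
cross-validation, matching the evaluated clinical procedure; because the
in-sample fit nests the cytology-only model, the combined AUC virtually
never falls below cytology alone, and the tests assert this across
replicates). Paired AUCs are compared with the DeLong covariance and a
two-sided normal test; degenerate variance returns p = 1.

The ROC sample-size computation is the binormal variance-function
method: `a = sqrt(2) qnorm(theta)`,
`V(theta) = 0.0099 exp(-a^2/2) (6 a^2 + 16)`, and
`n = (z_{1-alpha/2} sqrt(V(0.5)) + z_{power} sqrt(V(theta)))^2 /
(theta - 0.5)^2`, rounded to the nearest integer (the only rounding rule
consistent with both published reference values, 40 cases per group at
theta = 0.70 and 73 at theta = 0.65). The returned count is per group;
whether a published "number of cases" means per group or total is
ambiguous, and per group is the documented reading.

# Prognostic statistics

Kaplan-Meier estimates, log-rank tests and Cox models delegate to the
`survival` package (Efron ties by default; Breslow available). The
outcome-based cutpoint scan considers midpoints between consecutive
distinct marker values whose split leaves at least `minGroupFrac`
(default 0.10) of patients on each side, and picks the maximal two-group
log-rank chi-square; the statistic for all cutoffs is computed in one
vectorized pass, which makes the permutation correction affordable. The
uncorrected p (maximal statistic referred to chi-square(1)) is reported
because that is what outcome-based cutpoint software prints, but it is
anti-conservative by construction; the min-p corrected p permutes the
marker against the (time, event) pairs and ranks the observed maximum
among permutation maxima. The tests assert both facts on null
simulations: uncorrected rejection well above the nominal 5%, corrected
rejection within [0.02, 0.08]. Risk-group orientation is explicit per
marker: low circularity and low solidity are the risk groups, high
fractal dimension is. The multivariable Cox model adjusts for age >= 55,
endometrioid histology and the number of cell clusters; survival subsets
(`ec`, `em`, `em_g2_g3`) mirror the standard reporting panels.

# The synthetic cohort generator

Patient images of this kind are not publicly deposited, so validation
runs on a generator that emulates the statistical structure the analysis
assumes, with these frozen study conditions:

* **Clinical metadata** follow the published 200-patient cohort: class
  counts 92/13/17/43/18/10/7 (Normal, EH, AEH, EM G1, G2, G3, Others),
  class-conditional normal ages truncated at 18 y with the published
  means and SDs (e.g. Normal 49.9 (12.2), EM G1 59.2 (10.6)), and
  cytology drawn from the class-conditional three-tier frequencies of
  the same cohort. Cytology is conditionally independent of morphology
  given histology, which keeps "adjusted for cytology" a meaningful
  test.
* **Cluster boundaries** are star-shaped:
  `r(theta) = R_e(theta) (1 + a sum_k k^{-beta} (u_k cos k theta + v_k
  sin k theta))`, an ellipse modulated by a random Fourier series with
  amplitude `a` and spectral decay `beta`; `u_k, v_k` are fixed by the
  seed, so every mask is reproducible. Amplitudes large enough to drive
  `r <= 0` raise an error rather than clipping. Benign classes draw
  smooth, nearly elliptical clusters (a in [0.02, 0.10], beta 2) at
  Poisson mean 4 clusters per field; malignancy increases roughness,
  eccentricity, cluster count (up to lambda 5.86) and radius. A
  patient-level amplitude offset (SD 0.05) models between-patient
  heterogeneity; without it, five-field averaging makes the shape
  descriptors separate classes almost perfectly.
* **Rendering**: dark clusters (gray ~N(80, 8)) on a bright background
  (~N(215, 6)) — polarity is explicit config — placed without overlap
  and with a one-pixel gap (thin-layer preparations spread clusters;
  allowing contact would merge ground-truth components under
  8-connectivity). No blur is applied, so thresholding recovers the
  ground-truth masks and labeling can be tested exactly. Fields are
  256 x 256 px, chosen with the cluster radii (9-21 px) to keep a
  five-field specimen measurable in well under a second; photorealistic
  staining texture is out of scope.
* **The fractal-dimension design value.** Class-conditional count and
  size were calibrated once, on seeds disjoint from every test seed,
  so that the measured specimen fractal dimension separates the pooled
  diagnostic classes with AUC 0.85 (measured 0.844-0.861 across three
  n = 400 calibration cohorts), then frozen. The companion feature-level
  generator (`generateFeatureCohort()`, used by the statistical
  calibration suites where images would add nothing) draws specimen
  features directly from class-conditional normals whose fractal
  dimension separation is binormal AUC = 0.85 exactly.
* **Survival** is exponential with log-hazard linear in the
  standardized measured circularity (-0.8), solidity (-0.5) and fractal
  dimension (+0.6), independent exponential censoring (0.008/month) and
  an administrative horizon of 120 months — the simplest generative
  model that supports Cox parameter-recovery tests. No claim is made
  about real event-time distributions.

What passing tests on this cohort do and do not show: they validate the
estimators, the statistical machinery and the end-to-end plumbing under
a known generative model; they do not validate clinical effect sizes,
staining variability, focus artifacts, overlapping clusters or
menstrual-cycle morphology, none of which the generator emulates.

# Numerical choices and degenerate inputs

* Every stochastic stage derives its seed deterministically from the
  master seed and a stage tag (`deriveSeed()`), so one integer
  reproduces the entire study byte for byte.
* Thresholding a constant or near-unimodal image yields all-background
  plus a flag; an empty field has undefined descriptor means and an
  undefined fractal dimension, and a specimen whose every field is
  empty has no summary.
* Collinear components get a flagged degenerate ellipse (minor axis from
  the corrected moment only); single-pixel hulls are rejected by the
  Feret computation.
* Complete separation in logistic fits and monotone likelihood in Cox
  fits are detected and flagged; duplicated covariates raise an error.
* Problem sizes in the validation suites (n = 400 image cohort at 256 px
  fields, 500 null replicates for the rejection-rate checks, 99-200
  permutations for min-p corrections, 100 replicates for coverage
  checks) were chosen as the smallest sizes at which the asymptotic
  approximations under test are expected to hold.

# Known limitations

Bit-exact compatibility with any specific desktop tool's perimeter,
ellipse or box-counting internals is a non-goal (conventions above are
documented instead). The angle descriptor is axial but enters models in
raw degrees, mirroring the evaluated clinical analysis. The cutpoint
correction is permutation-based and therefore stochastic at fixed B. The
generator's class-conditional morphology is a stylized two-parameter
family; real cluster texture (nuclear overlap layers, chromatin) is not
modeled, and conclusions about real patients cannot be drawn from the
synthetic study.
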