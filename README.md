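# cytocluster

Quantitative cell-cluster morphometry for liquid-based endometrial
cytology, with the downstream statistics used to evaluate cluster shape as
a diagnostic and prognostic marker for endometrial cancer (EC) and
atypical endometrial hyperplasia (AEH).

## The problem

Endometrial cytology is a non-invasive alternative to biopsy, and
thin-layer (liquid-based) preparations make the architecture of shed cell
clusters visible at low magnification: benign clusters are smooth and
compact, malignant clusters show irregular protrusions and rougher
outlines. `cytocluster` turns that qualitative observation into numbers.
For each microscope field (8-bit grayscale, five fields per specimen) it:

1. binarizes the image (isodata intermeans by default, Otsu or a fixed
   threshold optionally) and labels connected clusters above a minimum
   area (`binarize()`, `labelClusters()`);
2. measures each cluster: area, perimeter (chain code with sqrt(2)
   diagonal weighting), circularity 4*pi*A/P^2, moment-based fitted
   ellipse (major, minor, angle), solidity A/A_hull, and maximum/minimum
   Feret diameters by rotating calipers (`clusterFeatures()`);
3. measures the field's box-counting fractal dimension, the negative
   slope of log N(eps) against log eps over occupied grid boxes
   (`boxCountFD()`), and averages everything over the five fields to one
   row per specimen (`summarizeSpecimen()`).

Specimen features then feed the clinical statistics: logistic odds ratios
for EC+AEH versus benign histology, unadjusted and adjusted for
postmenopausal age (>= 55 y) and the three-tier cytology result
(`fitLogisticOR()`); ROC curves with DeLong confidence intervals and
Youden cutoffs (`rocCurve()`); the paired DeLong test for whether adding
a morphometric feature to cytology improves the AUC (`combinedScore()`,
`delongTest()`); the binormal ROC sample-size computation
(`aucSampleSize()`); and overall-survival analyses — outcome-based
optimal cutpoints with a permutation min-p correction
(`optimalCutpoint()`), Kaplan-Meier/log-rank (`kmEstimate()`,
`logrankTest()`) and Cox models (`coxFit()`).

Because no public image set of this kind exists, the package ships a
seeded synthetic cohort generator (`generateCohort()`): star-shaped
cluster boundaries r(theta) = R_e(theta) (1 + a * sum_k k^-beta (u_k cos
k*theta + v_k sin k*theta)) with class-conditional roughness, count and
size; clinical metadata calibrated to a published 200-patient cohort
(class counts, ages, cytology cross-tabulation); and exponential survival
whose log-hazard is linear in the standardized measured features. The
generator's class-conditional morphology is calibrated so the specimen
fractal dimension separates the diagnostic classes with a design AUC of
0.85. Analytic fractal fixtures (Sierpinski carpet and triangle, Koch
island, line, square) validate the box-counting estimator
(`referenceShape()`).

## Worked example

```r
library(cytocluster)
report <- runFullStudy(studyConfig(cohortConfig()))  # 200 patients, ~90 s
print(report)
```

```
Synthetic cytology study report (seed 20260923 )
patients: 200  events: 70
ROC AUCs:
  perimeter          0.969 (0.945-0.993)
  ...
  circularity        0.998 (0.995-1.000)
  solidity           0.987 (0.971-1.000)
  fractal_dimension  0.877 (0.830-0.924)
```

Each AUC is the discrimination of one specimen-level descriptor for
EC+AEH versus benign histology with its DeLong 95% CI; on this synthetic
cohort the shape descriptors separate the classes strongly (only the
fractal dimension's separation is pinned to a design value). Adding a
feature to cytology (in-sample combined logistic score versus the
cytology flag alone):

```r
report$combined
#             feature auc_combined auc_cytology            p
# 1       circularity    0.9982957    0.6333333 5.746670e-64
# 2          solidity    0.9900752    0.6333333 1.507649e-59
# 3 fractal_dimension    0.9120802    0.6333333 2.633558e-28
```

Survival in the cancer subset, low solidity as the risk group:

```r
report$survival$solidity$ec$cutpoint
# Optimal cutpoint 0.9149 (19 low / 59 high, risk group = low marker)
# log-rank chi-square 72.665, uncorrected p 1.537e-17, min-p corrected p 0.004975
```

The uncorrected p treats the maximal log-rank statistic as a single
chi-square(1) and is anti-conservative by construction; the corrected
value comes from a permutation of the marker against the outcomes.
(Markers enter models per unit, so odds and hazard ratios for
[0,1]-valued markers such as solidity are numerically extreme.)

The ROC sample-size computation used to justify a cohort of this size:

```r
aucSampleSize(0.70)   # 40 cases per group
aucSampleSize(0.65)   # 73 cases per group
```

A thin command-line front end (`inst/scripts/cytocluster`) exposes
`simulate`, `extract`, `diagnose`, `prognose` and `run-all` over
YAML configs, PNG images and CSV tables.

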