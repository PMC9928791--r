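---
title: "PET transformation scoring: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PET transformation scoring: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petscore)
```

## The scoring model

A patient's PET study is reduced to three quantities: the global SUV-max
(the highest standardized uptake value over all lesions, dimensionless),
the total lesion glycolysis TLG (metabolic tumor volume × mean SUV of the
segmented volume, reported in cc-scaled SUV·cc), and a binary serum LDH
elevation flag. The transformation score is their product,

$$\mathrm{score} = \mathrm{SUV_{max}} \cdot \log_{10}(1 + \mathrm{TLG})
\cdot K_{\mathrm{LDH}},$$

with $K_{\mathrm{LDH}} = 2$ when LDH is elevated above the laboratory
reference and $1$ otherwise. The multiplicative form is deliberate: it
lets either a low-burden/high-avidity lesion (high SUV-max, modest TLG) or
a high-burden/low-avidity disease state drive the score up, while the
base-10 logarithm damps the marginal influence of ever-larger volumes and
keeps the TLG term on the same order of magnitude as SUV-max. The exact
algebraic consequences — strict monotonicity in each PET factor, score
zero iff SUV-max or TLG is zero, linear scaling in SUV-max, exact doubling
under LDH elevation — are asserted to 1e-12 in the test suite.

An **unknown LDH** maps to $K=1$. LDH is frequently unavailable at the
low-grade time point, yet scores must still be computable for every
record; mapping unknown to the non-inflating factor is the only default
that never manufactures evidence of transformation. Every defaulted
record is counted (`ldh_factor()` attaches the count, and
`run_pipeline()` logs it) so the imputation is never silent. For
post-transformation scans the flag supplied should be the LDH measured at
the scanned time point; the per-record interface leaves that decision to
the caller.

## Lesion segmentation and PET metrics

`segment_threshold()` implements fixed-fraction thresholding: the ROI is
the 26-connected set of voxels with SUV at or above 41% of the lesion's
*local* SUV-max. Numerical conventions, chosen once and stated here
because several are genuinely free:

* **Connectivity is 26-neighbour** (the most permissive standard 3D
  connectivity); comparison is **inclusive** (`>=` the threshold); voxel
  membership is by voxel-center containment; coordinates are 1-based grid
  indices, the natural R convention.
* The threshold refers to the **site's own maximum**, not the seed value
  or the global patient maximum. Since the region depends on the maximum
  and vice versa, the pair is iterated (grow, re-take the max) to a fixed
  point; the iteration is monotone in the local max and in practice
  terminates in two or three passes.
* TLG is computed **per ROI and summed** across a patient's lesions
  (global SUV-max, summed MTV, summed per-ROI TLG); the alternative —
  total MTV × a single global SUV-mean — is not the default because
  summing per-site quantities is the natural reading of per-site
  segmentation, but `compute_patient_metrics()` exposes everything needed
  to form it.
* No partial-volume correction and no SUV re-normalization: input volumes
  are assumed already SUV-valued.

`segment_gradient()` is a deliberately simple stand-in for commercial
gradient-based edge detection (it is *not* a re-implementation of any
proprietary tool): SUV is sampled by trilinear interpolation along ~200
radial rays from the hill-climbed local-max voxel, and each ray is cut
where the central-difference gradient magnitude (per mm) peaks. Two
properties are worth knowing. On sharp-edged lesions it agrees with the
41% threshold to within voxelization error (both recover a digital
sphere's volume within 10%). On smooth profiles the maximal-gradient
surface is the *inflection shell*: for an untruncated Gaussian of SD
$\sigma$ that shell (radius $\sigma$) lies strictly inside the 41%
isocontour (radius $1.335\sigma$), so a pure gradient rule under-segments
smooth blobs. The package's Gaussian phantom profile is truncated at the
lesion radius, and the truncation cliff dominates the inflection gradient
whenever $\sigma$ exceeds about $e^{1.5}$ sampling steps — in that regime
the gradient ROI lands between the 41% ROI and the full support, which is
what the test asserts.

Degenerate inputs are errors, not guesses: a seed voxel with SUV 0 is an
empty lesion, an out-of-bounds seed is a bounds error, and a flat
neighbourhood (no gradient anywhere) is a degenerate lesion for the
gradient method.

## The synthetic-cohort generator

No per-patient data are distributable, so the package carries a generator
whose defaults encode the published group summaries and make every
downstream stage testable. Each group is a `cohort_spec`:

* **Marginals are log-normal.** PET metrics are positive and strongly
  right-skewed, and the available summaries are an arithmetic mean plus an
  observed range — enough to pin down two parameters. The log-range is
  equated to the expected range of $n$ normal draws using the Blom
  approximation for the expected maximum order statistic,
  $z_n = \Phi^{-1}\!\left(\frac{n - 0.375}{n + 0.25}\right)$, giving
  $\sigma_{\log} = \frac{\ln \mathrm{hi} - \ln \mathrm{lo}}{2 z_n}$, and
  the log-mean is then chosen so the implied arithmetic mean equals the
  published mean *exactly*: $\mu_{\log} = \ln m - \sigma_{\log}^2/2$.
* **Dependence is a Gaussian copula** between the latent scores of
  SUV-max and TLG, with correlation `copula_rho = 0.5` committed as the
  package constant. The joint SUV-max/TLG distribution is nowhere
  published; 0.5 encodes the qualitative observation that the two metrics
  correlate but separate two distinct disease phenotypes. Notably, each
  metric's *own* discriminative ability (its single-metric AUC) is a
  functional of the marginals only and is completely insensitive to this
  choice — the copula affects only joint quantities such as the score
  distribution — so there is nothing in the published single-metric AUCs
  that could identify it more finely.
* **LDH elevation** is Bernoulli with the published elevated/available
  fractions: 6/44 (controls), 2/31 (pre-transformation), 28/47
  (post-transformation). Records with *unavailable* LDH are not generated
  by default; an optional `p_ldh_missing` reproduces availability
  fractions when missingness itself is under study.
* **Times** (control follow-up, case time-to-transformation) are
  log-normal calibrated the same way to means of 96.0 and 100.9 months.
* **Schema-only fields.** MTV is back-filled as TLG divided by an
  SUV-mean proxy of `0.5 * suvmax`, and the ROI count is uniform over a
  per-group integer range matched to the published medians. Both exist
  for schema completeness; neither feeds the score.

The discovery preset generates 53 controls, 53 post-transformation cases
and the 28-patient pre-transformation subset; the validation preset
generates 8 controls and 15 transformed patients from that cohort's own
summaries. The validation control group's published mean TLG (1664 cc)
is far above the discovery control mean (368.58 cc); the presets follow
each cohort's own numbers without attempting to reconcile them. The
validation preset's LDH probabilities and time distributions are not
separately published and reuse the discovery values.

**What the generator does and does not emulate.** It matches group sizes,
marginal locations/spreads, LDH rates and a plausible dependence
structure. It does not emulate case-control matching artifacts, histology
mix effects on PET metrics, scanner/protocol drift, intra-patient
correlation between time points, or measurement error in segmentation —
so tests passing on synthetic cohorts demonstrate that the *pipeline* is
correct and that the published operating characteristics are consistent
with the published summaries, not that the score would achieve them
prospectively on new patients.

One consequence deserves emphasis: the additive logistic comparator is
*refit per cohort*, so on synthetic data it adapts to whatever the
generator produced and its in-sample AUC sits essentially at the score's
(both ≈ 0.92 on discovery-preset cohorts, which brackets the published
0.91 vs 0.883 ordering on average but not replicate-by-replicate — the
score's AUC exceeds the refitted comparator's in only about half of
simulated cohorts). A fixed multiplicative formula beating a refit
three-parameter model on *real held-out* data is a statement about those
data that marginal-calibrated simulations cannot be forced to reproduce.

## Evaluation machinery

* **AUC** is the Mann–Whitney statistic with half-credit for ties,
  computed from ranks; the ROC curve is generated by the decision rule
  "score ≥ threshold ⇒ transformed" at every unique observed score. The
  trapezoid area under that curve is the same number, and the suite
  asserts equality to 1e-12 on 1000 random instances.
* **Bootstrap validation** is a class-stratified nonparametric bootstrap
  of patients (class sizes preserved, so every replicate is evaluable)
  with a percentile 95% CI — the simplest resampling procedure consistent
  with reporting a "mean AUC" plus CI. Model-vs-component comparisons use
  *paired* resamples (identical indices for both score vectors), with
  two-sided p-value $2\min(\Pr(\Delta \le 0), \Pr(\Delta \ge 0))$ floored
  at $1/n_{\mathrm{iter}}$, since an empirical p of exactly 0 is not
  reportable.
* **Threshold selection** searches the midpoints between adjacent
  distinct observed scores plus $\pm\infty$ (so round published-style
  integers are representable), maximizing sensitivity subject to a
  *required, explicit* minimum specificity; ties break toward higher
  specificity, then lower threshold. The criterion actually used to pick
  the published threshold is not stated anywhere, which is why
  `min_specificity` is a mandatory argument rather than a default.
* **Simple tests**: two-sided Fisher's exact and unpaired t
  (Student/Welch) delegate to the standard R implementations behind a
  stable interface; zero-variance t-test inputs resolve to the documented
  limit (p = 1 for equal means, p = 0 otherwise). Significance is
  two-tailed at 0.05 throughout and no multiplicity correction is
  applied, matching the analysis style the package reproduces.
* **Logistic fitting** is IRLS with convergence when the largest
  coefficient change drops below 1e-8 (cap 100 iterations). Complete or
  quasi-complete separation — diverging coefficients with fitted
  probabilities pinned at 0/1 — is detected and flagged, and the reported
  coefficients come from a ridge-stabilized refit (penalty 1e-6), keeping
  every fit finite and reproducible. Constant predictors are dropped and
  reported with coefficient exactly 0. `stats::glm()` serves as an
  independent cross-check in the tests, never as the implementation.

## Case-control matching

`match_controls()` is a greedy stand-in for a matching process whose
mechanics were never published: the pool is partitioned by histology and
each case must be paired with a control of the same histology (which
equalizes the FL fraction exactly), then within each stratum cases are
matched without replacement to the control with the nearest follow-up
time, hardest-to-match extremes first. Its quality is asserted the same
way a study would: balance checks (t-test of matched times typically
p > 0.05 at discovery scale; matched imbalance no worse than a random 1:1
draw across seeded trials), not optimality claims.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit integer seed, and the pipeline
derives per-stage seeds from one root via named substreams
(`substream_seed()`), so a configuration reproduces byte-identical
reports. The packaged experiments use: 100 seeded discovery cohorts
(53 + 53) for mean AUC and fixed-threshold sensitivity/specificity; 20
cohorts × 1000 bootstrap replicates for the bootstrap mean; 200 seeded
validation cohorts (8 + 15); 500 simulated binormal datasets
(100 + 100, 500 replicates each) for CI-coverage checks; and n = 10,000
draws for generator calibration checks. These sizes put Monte-Carlo error
comfortably inside the tolerances being asserted while keeping a full run
on a single CPU in the tens of seconds.

## Known limitations

* The gradient segmenter is a documented approximation; on smooth,
  untruncated intensity profiles it stops at the inflection shell and
  will under-segment relative to 41% thresholding.
* The generator's marginals are exactly log-normal by construction;
  real PET metric distributions may have different tail behaviour than a
  mean + range calibration can capture, and TLG's heavy tail
  (σ_log ≈ 1.6) makes small-cohort empirical means noisy.
* Scores for patients missing LDH are conservative lower bounds (factor
  1), which depresses sensitivity in cohorts with poor LDH availability.
* Matching is greedy, not optimal; it is evaluated by balance checks
  only.
* Survival analysis (overall survival, competing-risk regression of
  transformation) is intentionally out of scope.
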