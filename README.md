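# petscore

Low-grade (indolent) lymphomas — follicular lymphoma above all — carry a
1–3% annual risk of transforming into an aggressive large-cell histology.
Deciding whether a patient's disease has transformed usually requires a
biopsy, which may be infeasible or miss the transformed component.
`petscore` implements a noninvasive, FDG-PET-based alternative: a
transformation score built from the patient's PET metrics and serum LDH,
together with the full evaluation machinery needed to study it, for
biostatisticians and imaging researchers working on lymphoma risk
stratification.

## The model

For a patient with global maximum standardized uptake value
SUV<sub>max</sub>, total lesion glycolysis TLG (in cc-scaled SUV·cc), and
serum lactate dehydrogenase status, the score is

```
score = SUVmax × log10(1 + TLG) × K_LDH ,   K_LDH = 2 if LDH elevated, else 1
```

SUV<sub>max</sub> captures lesion avidity, the damped `log10(1 + TLG)`
term captures disease burden on a comparable scale, and their product lets
either low-burden/high-avidity or high-burden/low-avidity disease raise
the score. Patients are classified as transformed when the score meets a
decision threshold (75 score units is the recommended high-specificity
operating point).

The package provides:

* **PET metrics** — lesion segmentation on SUV volumes (41%-of-SUV-max
  threshold with a self-consistent local maximum, plus a simplified
  gradient method), per-lesion SUV-max / SUV-mean / MTV / TLG, and
  per-patient aggregation (`segment_threshold()`, `segment_gradient()`,
  `compute_patient_metrics()`, NIfTI I/O via `read_pet_volume()`).
* **Scoring** — `transformation_score()`, the additive logistic comparator
  `fit_additive_logistic()` (IRLS with separation detection and a ridge
  fallback), and the logistic probability-of-transformation curve
  (`probability_curve()`).
* **Evaluation** — `roc_auc()` (tie-corrected Mann–Whitney AUC),
  class-stratified `bootstrap_auc()` with percentile CIs, paired
  `compare_auc_bootstrap()`, specificity-constrained `select_threshold()`,
  `fishers_exact()` and `two_sample_t()`.
* **Design** — 1:1 case-control matching on histology and follow-up time
  (`match_controls()`).
* **Synthetic cohorts** — `generate_cohort()` draws patients from
  log-normal SUV-max/TLG marginals coupled by a Gaussian copula,
  calibrated from published group means and ranges via
  `calibrate_lognormal()`; `discovery_preset()` / `validation_preset()`
  encode the study conditions, and `generate_phantom()` builds digital PET
  phantoms with ground-truth masks for the segmentation code.
* **Pipeline** — `run_pipeline()` composes simulate/ingest → score →
  evaluate → report; `inst/cli/petscore.R` is a thin command-line wrapper
  with `simulate`, `metrics`, `score`, `evaluate`, `match` and `run` verbs.

## Worked example

```r
library(petscore)

# log-normal parameters from a published "mean 8.71 (range 1.70-22.57)", n = 53
calibrate_lognormal(8.71, c(1.70, 22.57), 53)
#> $mu_log    2.001622
#> $sigma_log 0.5707013

# the score at the post-transformation group means, LDH elevated
transformation_score(22.03, 3256.18, TRUE)
#> [1] 154.7758

# end-to-end run on a synthetic discovery-style cohort (53 vs 53)
run_pipeline(list(preset = "discovery", seed = 1))
#> petscore run: synthetic:discovery | n = 134
#>   score AUC 0.928 | bootstrap mean 0.929 (95% CI 0.878-0.972)
#>   operating point: thr 72.85 sens 0.566 spec 0.981 | fixed thr 75: sens 0.547 spec 0.981
#>   component AUC: SUV-max 0.892, TLG 0.853 | additive model 0.920
```

Reading the output: on this simulated cohort the score separates
post-transformation scans from controls with AUC 0.93 (bootstrap 95% CI
0.88–0.97); thresholding the score at 75 units classifies transformation
with 55% sensitivity at 98% specificity; and the score outperforms either
PET metric alone. (The 134 records include the 28-patient
pre-transformation subset, which is summarized descriptively and excluded
from the ROC contrast.)

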