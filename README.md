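# gaitsym

Quantify left–right gait symmetry from stance-phase vertical ground
reaction force (GRF) recordings.

`gaitsym` is aimed at biomechanics and clinical gait researchers working
with force-platform data. It implements, side by side:

* the **classical per-parameter protocol**: reduce each stance curve to
  the six discrete gait parameters (peak forces `Fz1`, `Fz3`, valley
  `Fz2` in %BW; their times `Tz1`, `Tz2`, `Tz3` in % of stance), then
  judge symmetry by trial repeatability (coefficient of variation,
  acceptable at CV <= 12.5 %), Robinson's absolute symmetry index

  SI = 2 |X_R − X_L| / (X_R + X_L) × 100 %   (acceptable below 10 %),

  and a paired t-test across subjects (significant at p <= 0.05);

* a **classification-based assessment**: treat each 101-point
  bodyweight- and time-normalized stance curve as one observation, train
  a soft-margin kernel SVM (solved in-package by sequential minimal
  optimization) to discriminate left from right, and read cross-validated
  accuracy as an asymmetry measure — under the symmetry hypothesis left
  and right curves share one distribution and no classifier can beat
  chance. A within-subject permutation test converts the accuracy into a
  p-value, and `1 − 2·max(acc − 0.5, 0)` into a symmetry score in [0, 1];

* a **synthetic cohort generator** emulating two-peak vertical GRF
  waveforms (60 subjects × 10 trials/side at 400 Hz by default,
  per-parameter CVs in the 4–10 % range typical of healthy elderly
  cohorts, controllable
  left–right asymmetry), so the entire pipeline is testable without
  force-platform hardware.

## Worked example

Simulate a small cohort with a 10 % right-side overload of the first
peak, preprocess, and run both protocols:

```r
library(gaitsym)

cohort <- sample_cohort(cohort_config(
  n_subjects = 12, trials_per_side = 10,
  asymmetry = c(fz1 = 0.10), seed = 1))
patterns <- preprocess_trials(cohort$trials)

report <- build_si_report(extract_discrete_params(patterns))
print(report)
#> Left-right symmetry report (12 subjects, SI mode: per_subject)
#> Param  CV_L(%)   mean_L  CV_R(%)   mean_R   SI(%)        p  flags
#> Fz1       7.37   116.70     8.48   128.87    9.90   0.0000  p*
#> Tz1       9.96    24.56     9.14    24.40    4.17   0.6416
#> Fz2       6.41    74.93     6.44    74.70    2.17   0.6652
#> Tz2       5.25    48.79     5.33    48.88    2.67   0.8573
#> Fz3       8.79   110.96     8.65   111.64    3.64   0.6394
#> Tz3       5.12    74.47     5.10    74.11    1.65   0.4796
```

Every CV sits under 12.5 % (repeatability acceptable) and every SI under
10 % — by the classical thresholds this cohort "looks symmetric" — yet
the injected `Fz1` overload shows as an SI of 9.90 % (close to its
closed form 2·0.1/2.1 = 9.5 %) with a significant paired t-test. The
classifier view of the same cohort:

```r
cv <- cross_validate(patterns, feature_mode = "six_params",
                     kernel = rbf_kernel(), cost = 1,
                     k = 6, repeats = 10, seed = 1)
print(cv)
#> 6-fold CV x 10 repeats | features: six_params | kernel: rbf(auto width) | C=1 | n=24
#> (ACC, SEN, SEP) = (0.754, 0.625, 0.883)   accuracy SD 0.181

print(symmetry_score(patterns, feature_mode = "six_params",
                     kernel = rbf_kernel(), n_permutations = 19, seed = 1))
#> symmetry score 0.500 (mean CV accuracy 0.750), permutation p = 0.0500 (19 permutations)
```

Cross-validated accuracy well above chance marks the cohort as
asymmetric (score 0.5, permutation p at its 19-permutation floor of
0.05). On a zero-asymmetry cohort the same pipeline hovers at accuracy
~0.5 and score ~1. `rbf_kernel()` with no width resolves sigma per
training fold by the median-distance heuristic.

A command-line wrapper over the same functions ships with the package
(`system.file("cli", "gaitsym.R", package = "gaitsym")`) with
subcommands `simulate`, `preprocess`, `si-report`, `classify`, `grid`
and `score`; see the methods vignette (`vignettes/gait-symmetry.Rmd`)
for the modelling details and design decisions.

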