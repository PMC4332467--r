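---
title: "Quantifying gait symmetry: classical indices and classification-based assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gait symmetry: classical indices and classification-based assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gaitsym)
```

## The problem

In healthy walking the vertical ground reaction force (GRF) under each
foot traces a characteristic two-peak "M" shape across the stance phase:
a loading-response peak shortly after heel strike, a mid-stance valley,
and a push-off peak before toe-off. Clinicians treat left–right symmetry
of these curves as an indicator of intact gait function, and deviations
from symmetry as an early marker of at-risk gait, particularly in elderly
populations.

Two families of methods quantify that symmetry. The *classical protocol*
reduces each curve to six discrete parameters — the two peak forces, the
valley force (`Fz1`, `Fz2`, `Fz3`, in percent bodyweight) and their
occurrence times (`Tz1`, `Tz2`, `Tz3`, in percent of stance) — and asks,
parameter by parameter, whether left and right differ: trial-to-trial
repeatability via the coefficient of variation (CV, acceptable at or
below 12.5 %), Robinson's absolute symmetry index

$$\mathrm{SI} = \frac{2\,|X_R - X_L|}{X_R + X_L}\times 100\,\%$$

(conventionally acceptable below 10 %), and a paired t-test across
subjects (significant left–right difference at $p \le 0.05$).

The *classification-based* approach treats the whole 101-point normalized
stance curve as one observation and poses symmetry assessment as a binary
classification problem: if left and right curves are drawn from the same
distribution, no classifier can discriminate the sides above chance.
Cross-validated accuracy of a left-vs-right classifier therefore measures
asymmetry: accuracy near 0.5 means symmetric; accuracy near 1 means the
sides are systematically different — even when every per-parameter SI
looks innocuous. This package implements both protocols, the soft-margin
kernel SVM underlying the second one, and a synthetic cohort generator to
validate the whole chain.

## Data model and preprocessing

A *force trial* is one stance-phase recording of vertical force (Newtons)
with subject, side and trial identifiers, the platform sampling rate
(400 Hz by default) and the subject's bodyweight. Preprocessing has three
steps, each a separate function:

1. `normalize_bodyweight()` converts forces to percent bodyweight,
   $100 \cdot F / BW$, so a typical loading peak reads about 114 %BW.
   Negative raw samples (sensor noise around foot contact) are clipped to
   zero by default, since vertical GRF is physically non-negative.
2. `segment_stance()` crops away the near-zero padding that platform
   exports carry around the actual contact. Stance is the longest
   contiguous run of samples at or above a threshold (default 5 %BW),
   extended by one sub-threshold sample on each side to keep the onset
   and offset ramps. The threshold is a free choice — recordings of
   isolated platform steps rarely document one — so it is exposed as an
   argument.
3. `time_normalize()` interpolates the stance segment linearly onto 101
   equally spaced points covering 0–100 % of stance duration, endpoints
   included, so index $i$ is the force at $i$ % of stance. Linear
   interpolation is parameter-free and cannot overshoot between samples,
   which matters because the downstream feature extraction reads extrema
   off this grid. At 400 Hz a typical 0.7 s stance yields ~280 raw
   samples for 101 grid points, so no information of practical relevance
   is lost.

The resulting *gait pattern* — the classification unit — carries the
label +1 for right and −1 for left. One convention worth stating: curves
are normalized over the *stance phase* (the portion a single force
platform can record), not the full gait cycle.

```{r, eval = FALSE}
trials <- read_trials("trials.csv")
patterns <- preprocess_trials(trials, threshold_pct_bw = 5)
```

## The classical protocol

`extract_discrete_params()` locates the first peak inside a 5–40 %
window, the second peak inside 60–95 %, and the valley as the minimum
strictly between them, with ties broken by the earliest index. The
windows are not standardized anywhere; these defaults bracket the
timings observed in healthy cohorts (peaks near 23 % and 77 %, valley
near 49 %) with wide margins and are configurable. A curve without a
valley below both peaks (e.g. a single-bump curve from a shuffling gait)
raises an extraction error rather than returning nonsense.

`build_si_report()` aggregates per subject first: parameter means and
trial-to-trial CVs per subject and side, then averages across subjects.
The symmetry index is computed per subject from that subject's side
means and then averaged — not from the group means — because an SI of
group means washes out opposing asymmetries between subjects; the
group-means variant is available via `si_mode = "group_means"`. The
paired t-test runs across subjects on the subject-level side means, is
two-sided (the conservative convention when no direction is
pre-registered), and uses the n−1 standard deviation throughout, as does
every CV in the package. No multiple-testing correction is applied
across the six parameters, matching how such tables are conventionally
reported; readers should keep that in mind when counting "significant"
parameters.

## The support vector machine

The discriminator is a soft-margin SVM written in-package. Training
solves the standard dual

$$\max_{\beta}\; \sum_i \beta_i - \tfrac12 \sum_{i,j} \beta_i \beta_j
  y_i y_j K(x_i, x_j), \qquad 0 \le \beta_i \le C,\quad
  \sum_i \beta_i y_i = 0,$$

by sequential minimal optimization: repeatedly pick a pair of dual
variables, optimize them analytically subject to the box and equality
constraints, and update the bias. The first index of a pair is any
Karush-Kuhn-Tucker (KKT) violator at tolerance `tol` (default 1e-3); the
second maximizes the error difference among non-bound points, falling
back to randomized sweeps (seeded, so training is reproducible).
Termination requires every KKT condition to hold at `tol` *after* the
bias has been re-centered on the midpoint of its feasible interval —
with small cohorts it happens regularly that all dual variables end at a
bound, where the running bias estimate is not unique and a naive
convergence check can both miss true violators and chase phantom ones.
The decision function is $f(x) = \sum_{SV} \beta_i y_i K(x_i, x) + b$
with `sign(0)` mapped to +1.

Three kernels are provided: linear $x \cdot z$, polynomial
$((x \cdot z) + 1)^d$, and Gaussian RBF
$\exp(-\lVert x - z\rVert^2 / 2\sigma^2)$. When no RBF width is given,
$\sigma$ is resolved at training time as the median pairwise distance of
the training features — a width has to track the feature dimension (a
$\sigma$ suited to 6 standardized features leaves the Gram matrix
near-identity on 101 of them, collapsing the classifier to chance), so
no fixed numeric default is sensible across the three feature sets;
`grid_search()` sweeps explicit widths around it. The RBF exponent is
negative,
as it must be for a Mercer kernel (the form is sometimes misprinted
without the minus sign; with a positive exponent the "kernel" diverges).
The penalty exponent of the slack term is fixed at 1 — the plain hinge
loss — which is the only value under which the primal soft-margin
program is the standard convex one. Because RBF and polynomial kernels
are scale-sensitive, the classification pipeline z-scores every feature
with constants fitted on the training folds; this can be disabled.

Correctness is guarded two ways in the test suite: small random problems
are solved in parallel by an independent dense-QP oracle (an
interior-point solve, with a projected-gradient fallback) and the dual
objectives compared to 1e-4, and the KKT conditions are re-derived from
the trained model directly.

## The evaluation engine

`cross_validate()` reproduces the experimental design used for such
cohorts: balanced six-fold cross-validation repeated 10 times. Design
choices that the bare description leaves open, and how this package
resolves them:

* **One pattern per subject and side.** By default the repeated trials
  of a subject are averaged pointwise, so a 60-subject cohort yields 120
  patterns — 60 per class. A `per_trial` mode exists, but averaging is
  the default because repeated trials of one subject are far from
  independent.
* **Subject-paired folds.** Both sides of a subject land in the same
  fold (`pairing = "subject_paired"`), so a subject never contributes to
  both training and test; otherwise the classifier could exploit
  subject identity rather than side. A `pattern_level` mode mirrors the
  alternative reading.
* **Repeats are fresh partitions.** "Repeated 10 times" is read as 10
  independent re-shufflings of the fold partition; fold assignment is a
  deterministic function of the master seed through named sub-streams.
* **No leakage.** Standardization constants and, in `pca` mode, the PCA
  basis are fitted on the training folds of each split and frozen for
  the held-out fold. The test suite checks this bit-exactly by
  corrupting a held-out pattern and asserting that its fold's model does
  not move.

Three feature sets are compared: the full 101-point pattern
(`all_101`), the six discrete parameters (`six_params`), and PCA scores
(`pca`). For PCA the number of retained components is the smallest k
whose cumulative explained-variance fraction reaches a target (default
0.95) — there is no canonical component count for gait curves, so the
threshold is exposed rather than hard-coded. Performance is reported as
accuracy, sensitivity and specificity from the pooled confusion counts
per fold, with the right side as the positive class; a ratio with an
empty denominator is reported as `NA` with a flag, never silently as 0.

`symmetry_score()` condenses the premise into one number:
$s = 1 - 2\max(\bar a - 0.5, 0)$, where $\bar a$ is mean CV accuracy, so
1 is fully symmetric and 0 maximally asymmetric. Significance comes from
a permutation test that swaps the left/right labels within each
subject's pair — the exchangeability the symmetry hypothesis actually
asserts — with $p = (1 + \#\{a_{perm} \ge a_{obs}\}) / (1 + B)$. At
least 19 permutations are needed to resolve $p \le 0.05$.

`grid_search()` wraps the kernel/penalty/feature-mode sweep used to tune
$C$, $\sigma$ and $d$, ranking by accuracy with ties broken by
sensitivity, specificity, then smaller $C$. Note the protocol tunes and
evaluates on the same cross-validation — as is common in this
literature — so grid-searched accuracies are mildly optimistic; an outer
validation loop would be needed for an unbiased generalization estimate.

## The synthetic cohort generator

No public force-platform dataset accompanies the protocol, so the
package ships a generator whose defaults encode the study conditions
reported for healthy-elderly force-platform cohorts: 60 subjects, 10 trials per side, 400 Hz, population means
(114, 75, 110) %BW at (23, 49, 77) % stance, per-parameter trial-to-trial
CVs of roughly 4–10 % (`fz1` 8.4, `tz1` 10.1, `fz2` 6.4, `tz2` 5.3,
`fz3` 9.5, `tz3` 5.1), and a configurable multiplicative left–right
asymmetry applied to the right side.

The waveform is a monotone cubic Hermite spline through the knots
$(0, 0)$, $(T_{z1}, F_{z1})$, $(T_{z2}, F_{z2})$, $(T_{z3}, F_{z3})$,
$(100, 0)$ with zero derivative at the interior knots and endpoint
slopes at 1.5 times the secant (inside the Fritsch–Carlson monotonicity
region). This form was chosen because its local extrema *are* the six
nominal parameters, exactly and by construction — the one property the
rest of the pipeline depends on. Earlier experiments with sums of
Gaussian lobes required iterative re-calibration to pin the extrema and
became numerically fragile when the valley lobe drifted toward a peak.
The spline is smooth and M-shaped but makes no physiological claim
beyond its extrema: it has no impact-transient spike, no
double-support force sharing, and its curvature between knots is an
interpolation artifact.

Cohort sampling is hierarchical and CV-scaled: subject-level parameters
are drawn multiplicatively around the population means (between-subject
CVs default to the same per-parameter scale as the within-subject ones,
since between-subject spreads are rarely published), the right side is
the left side times $1 + \delta$ per parameter, and each trial jitters
the subject parameters with the within-subject CV. Multiplicative noise
is used because repeatability of these parameters is reported as CV;
additive noise would misrepresent how variability scales with magnitude.
Draws that would break curve validity (ordering of the three times, a
valley at or above a peak) are clamped, and a clamping rate above 1 % of
draws triggers a configuration warning. Stance duration is drawn at
0.7 ± 0.05 s per trial; it only enters through time normalization, so
its distribution is inconsequential by design — a property the tests
confirm rather than assume. Rendering converts %BW to Newtons with a
subject bodyweight drawn at 650 ± 65 N, pads the contact with zero-force
samples, and adds 2 N of white measurement noise.

Every subject consumes an independent, named seed sub-stream
(`substream_seed()`), so the same seed reproduces a cohort bit-for-bit
and enlarging a cohort never changes earlier subjects' draws.

What passing tests on this generator do **not** show: real GRF curves
differ from the spline between the extrema, real asymmetry is
heterogeneous across subjects rather than a fixed multiplicative shift,
and real trial noise is temporally correlated. Results on synthetic
cohorts validate the machinery and its statistical calibration, not
clinical performance.

## Numerical choices and degenerate inputs

* SMO: KKT tolerance 1e-3, box tolerance 1e-12, support vectors at
  $\beta > 10^{-8}$; flat or concave pair directions ($\eta \le 0$) are
  resolved by evaluating the dual at both box ends.
* Ties: earliest index for peak/valley plateaus; `sign(0)` is +1.
* A constant feature is centered but not scaled (scale 1) by the
  standardizer.
* CV of zero-mean values, SI with $X_R + X_L = 0$, and a paired t-test
  with identical non-zero differences are domain errors; all-zero
  differences return $t = 0$, $p = 1$.
* PCA drops numerically zero eigenvalues ($< 10^{-12}$ of the largest)
  before computing explained-variance fractions.
* Validation in the test suite runs at a reduced scale chosen to keep
  the statistics honest but cheap: 12-subject cohorts, 200 replicates
  for null calibration, 50 for the power comparison, 10 per point of the
  asymmetry dose-response.

## Known limitations

* The generator is calibrated to healthy-elderly walking; pathological
  waveforms (flat-top curves, missing push-off peak) will fail discrete
  extraction by design, and the classifier pipeline has not been
  exercised on them.
* Only the vertical GRF component is modelled; anterior–posterior and
  medio-lateral forces, kinematics and accelerometry are out of scope.
* Grid-searched accuracies are selection-biased (see above).
* The permutation test permutes whole subject pairs; with very few
  subjects its resolution is limited by $2^{n}$ possible relabelings.
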