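---
title: "Methods: sway-based ACL injury-risk screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sway-based ACL injury-risk screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swayrisk)
```

`swayrisk` turns raw shank-IMU and optoelectronic-bar recordings of
single-leg countermovement jumps (mCMJ) and single-leg squats (SLS) into a
13-feature description of leg stability, load absorption and leg mobility,
labels athletes with the Landing Error Scoring System (LESS), and
benchmarks classifiers that predict the label from the features. This
vignette documents the models, the tunable parameters, the synthetic-data
generator, and the numerical and design choices, so that every default can
be audited.

## Orientation estimation

A static upright trial defines the analysis frame:
`estimate_static_alignment()` rotates the time-averaged accelerometer
vector onto $(0, 0, +g)$ by the shortest arc. With a single 6-axis IMU,
heading (rotation about gravity) is unobservable, so it is pinned to zero
at calibration; the identity of the medio-lateral (ML) and
antero-posterior (AP) axes downstream inherits this convention. A mean
gyro magnitude above 5 °/s during the "static" trial is treated as
movement and rejected.

`mahony_orientation()` implements the classic complementary filter on the
unit-quaternion manifold: the gyroscope (°/s) is integrated exactly via
the exponential map, while the accelerometer's gravity direction feeds
back through a proportional–integral term,
$\omega_{corr} = \omega + K_p\, e + K_i \int e\,dt$ with
$e = \hat a \times \hat v$ (measured vs. predicted gravity direction in
the body frame). Defaults $K_p = 1.0\,\mathrm{s^{-1}}$,
$K_i = 0.3\,\mathrm{s^{-1}}$ are common general-purpose values — the gyro
dominates over ~1 s time scales, long enough that landing transients do
not corrupt tilt, short enough to curb drift. The magnetometer is ignored
throughout (6-axis fusion): heading plays no role in the features beyond
the axis convention above. Two numerical guards matter:

* the filter is initialized from the first-sample accelerometer tilt with
  zero heading, so trials that begin at rest start aligned;
* the accelerometer correction is gated off whenever
  $\bigl|\,\lVert a\rVert - g\,\bigr| > 0.4\,g$ (`accel_gate`), because in
  flight the specific force is near zero and during landing impacts it
  does not point along gravity; with the gate the filter coasts on the
  gyro through exactly those phases.

`project_vertical_axis()` maps orientation to the sway trace as the
intersection of the line along the sensor's vertical axis $S$ with the
horizontal plane 1 cm below the sensor origin:
$xy = -\,\mathrm{depth}\cdot(S_x/S_z,\; S_y/S_z)$ in cm. Line–plane
intersection (not orthogonal projection) is used because it reproduces the
"plane 1 cm below the sensor" geometry exactly and reduces to small-angle
proportionality; whether that plane should be fixed in the world or carried
with the sensor is underdetermined by the construction, and the world-frame
reading is our documented choice. The projection errors out if
$S_z \le 0.1$ (sensor nearly horizontal), naming the offending sample.

## Event detection

**Jump.** Ground contact is the first off→on transition of the
optoelectronic LED status after `search_from`. Stabilization is the first
*strict* local minimum of the rectified gyro magnitude after contact;
because the raw rectified signal is minima-ridden, it is smoothed first
with a zero-phase 4th-order Butterworth low-pass (default cutoff 10 Hz,
configurable). Plateaus resolve to their earliest sample, and candidate
minima inside the trailing 0.12 s of the trial are ignored because the
zero-phase filter rings at the series boundary. `Ts` is the minimum's time
minus the contact time.

**Squat.** The descent starts when the rolling standard deviation of
$\lVert(\theta_x, \theta_y, \theta_z)\rVert$ exceeds $k = 5$ times its
average on the static trial, and ends at the maximum of $\theta_y$ (the
approximate knee-flexion axis); `T_DP` is the difference and
$\theta_{y,max}$ the peak. The rolling SD uses a trailing window of 0.5 s
evaluated at *every* sample. A hopped window (e.g. 50% overlap) would
quantize the detected start to 0.25 s, which is incompatible with
recovering `T_DP` to within a few hundredths of a second; evaluating the
same statistic densely preserves the rule while giving sample-level
resolution. Whether the SD rule was originally meant as sliding or
cumulative is not determinable; the sliding form is implemented.

## Features

Path lengths follow the standard posturographic definitions
(`PL`, `PL_AP`, `PL_ML` as sums of step norms/components, cm), and the
ellipse area is $EA = 2\pi F(\ell; 2, n-2)\sqrt{s_x^2 s_y^2 - s_{xy}^2}$
with the coverage level $\ell = 0.99$ by default (the $F$ quantile
generalizes the classic 95% construction). A collinear point cloud yields
$EA = 0$ with a warning rather than an error, since a perfectly planar
oscillation is a legitimate degenerate sway.

Load absorption rotates the accelerometer into the absolute frame with the
estimated orientation, subtracts gravity from the vertical channel, and
takes RMS of the vertical component and of the horizontal module over the
landing window. Gravity removal happens in the absolute frame because
otherwise the constant 9.81 m/s² dominates `RMS_z` and the group contrast
disappears.

Two window conventions were genuinely open:

* *Computation vs. normalization window.* The features are "normalized
  for" `Ts` / `T_DP`; the windows over which the raw quantities are
  computed are not separately specified. We compute over and divide by the
  same interval — the landing window for the jump, the descent for the
  squat — since that interval is the mechanically loaded one.
* *Pooled vs. per-repetition sway clouds.* Each repetition gets its own
  path lengths and ellipse, and the five repetitions are averaged
  (`build_feature_vector()`), matching the "averaged across the five
  jumps/squats" aggregation. Fewer than five repetitions require
  `allow_fewer = TRUE` and emit a warning.

Units follow the conventional labels (cm, cm², m/s², s, °) even though
time-normalization changes dimensions; the numbers stay comparable with
the published group tables.

## LESS aggregation

Items 1–15 are binary errors; items 16 (sagittal joint displacement:
soft/average/stiff) and 17 (overall impression) take 0/1/2, so the worst
landing scores 19. The per-jump score is the item sum; the median of the
three jumps is the athlete's score; `NR` iff median ≤ 5. The item-range
table is data (`less_item_ranges()`), not code constants.

## Classifier benchmark

The nine configurations are fixed: SVMs with polynomial kernels of degree
1/2/3 (box constraint $C = 1$, `coef0 = 1` for the curved kernels so the
polynomial is inhomogeneous); kNN with (k = 1, Euclidean, uniform votes),
(k = 10, cosine), (k = 10, Euclidean, squared-inverse-distance votes); and
Gini decision trees pruned back to at most 4/20/100 splits along the
complexity path. Only the kernel degrees, distances/k and split caps are
given by the study design; everything else is the library default.

Each fold standardizes features to zero mean/unit SD using training-fold
statistics only — distances are meaningless across features spanning
~0.2 cm² to ~250 m/s² — and a mutation-sentinel test verifies the test
fold cannot influence the scaler. Confusion counts are pooled (summed)
across folds and accuracy/F1/G computed on the pooled matrix; per-fold
averaged accuracy is available via `fold_average = TRUE`. Pooling is the
default because single per-classifier confusion matrices are the natural
summary of a cross-validation pass; metric-level averaging is a close
variant, not a different method.

Two readings of "9-fold cross-validation with 30 training and 9 validation
athletes" coexist for $n = 39$: disjoint stratified folds of size 4–5
(`grouped-9fold`, the default — every athlete tested exactly once) and
nine random 30/9 splits (`repeated-30-9`). Both are implemented; the
report records which was used.

Metric conventions: `NR` is the positive class. F1 is the harmonic mean of
recall and precision — note that algebraically
$F1 = 2TP/(2TP + FP + FN)$, so it is symmetric in the two error types at
fixed TP; the asymmetry between error kinds is carried by
$G = \sqrt{(1-\text{sens})^2 + (1-\text{spec})^2}$, whose attainable range
on rates is $[0, \sqrt 2]$. The goodness bands are optimum ($G \le 0.25$),
good, random and bad; the good/random/bad boundary is the chance
classifier's distance $\sqrt{0.5} \approx 0.707$, conventionally quoted as
0.70, and `goodness_category()` labels a value exactly at $\sqrt{0.5}$ as
"random".

## Feature importance and correlation

`mda_importance()` grows a random forest (default 500 trees, bootstrap
size $n$, $\sqrt p$ candidate features per split) with bag bookkeeping,
then for each feature permutes its values (one seeded global permutation
per repeat; `n_repeats` averages several) and measures, tree by tree, the
drop in out-of-bag accuracy; the mean drop × 100 is the MDA in percentage
points. A description of this procedure that refits the model with a
feature excluded exists in the literature, but it conflicts with the
standard OOB permutation scheme; the standard scheme is implemented, and a
test cross-checks it against the reference implementation's unscaled mean
decrease in accuracy. Zero-variance features get MDA 0 with a warning.
Features above the importance threshold (default 15 percentage points, the
conventional cut) are correlated with the LESS median score via Spearman's
rank correlation (mid-ranks, large-sample p-value); if no feature clears
the threshold — typical when informative features are strongly redundant,
because permuting one leaves its twins standing — the top four by rank are
used, matching the four-feature correlation analysis. Band boundaries
(0.1/0.3/0.6/1) are assigned to the lower-|r| band.

## The synthetic-data generator

No public cohort of this kind exists, so the generator defines the study
conditions at two levels.

**Feature level.** Each athlete's 13 features are drawn from their group's
multivariate Gaussian with the published means and SDs. The default
correlation structure sets $r = 0.7$ among the jump instability features
(`mcmj_pl_ml`, `mcmj_ea`, `mcmj_rms_z`, `mcmj_rms_xy`) and $r = 0.2$
elsewhere: several of those features separate the groups by many SDs
univariately yet carry small permutation importance, which is only
consistent with strong redundancy. Rows with any negative entry are
rejected and redrawn whole (no point mass at zero). With defaults, the
two groups are separated by several SDs in multiple features, so the
benchmark surrogate represents a cleaner, noise-free version of the
measurement process: classifiers reaching near-perfect pooled metrics on
it shows the pipeline machinery is sound, not that real athletes are this
separable.

LESS records are generated to be *consistent by construction* with the
labels: group score distributions are shifted binomials on the attainable
ranges (0–5 for `NR`, 6–19 for `R`) whose means match the requested group
means (defaults 3.5 and 7.5); a Gaussian copula couples each athlete's
score to their within-group ellipse-area percentile, and the copula
strength is chosen by a seeded internal pilot simulation (n = 2000, a grid
of candidate strengths) so the requested overall Spearman correlation
(default 0.88) survives integer quantization and the group constraints.
Jump-to-jump jitter scales with the group's score spread, so degenerate
targets (e.g. mean 0) produce identical jumps. Each jump score is
decomposed into 17 items by sampling `score` of the 19 unit slots without
replacement, which respects every item's range.

**Signal level.** Trials are additive-piecewise: stance, flight (LED off,
near-zero specific force), landing window, recovery — no musculoskeletal
dynamics. The landing sway is a designed planar shape (a blend between an
ellipse and a rounded-square tour, cycle count and blend chosen by
bisection/grid) sampled along its arc with a strictly decaying speed
profile whose minimum falls exactly on the last window sample, so the
stabilization-time rule finds `Ts` by construction; a heading spin with
the same envelope keeps the minimum detectable even for zero-sway recipes
(spinning about the vertical axis leaves the projection untouched). The
impact is a zero-mean high-frequency burst in the absolute frame, scaled
so the extracted RMS indices meet their targets; squats use a smooth
monotone flexion ramp with a mildly peaked apex plus downward-only dips
(which can never raise $\theta_y$ above the apex) and a tapered AP
oscillation. The generator calibrates itself against the package's own
extraction chain (a few outer iterations adjusting budgets, ramp duration
and burst scales), which is the point: the emitted trial's *extracted*
features equal the recipe targets, and the round-trip tests exercise the
full independent extraction path on the emitted signals.

Two published-value inconsistencies surface here and are reconciled
explicitly rather than silently:

* The group-mean jump path lengths violate the geometric constraint
  $\max(PL_{AP}, PL_{ML}) \le \sqrt{PL_{AP}^2 + PL_{ML}^2} \le PL \le
  PL_{AP} + PL_{ML}$ that every planar path obeys (one group has
  $PL < PL_{ML}$, the other $PL > PL_{AP} + PL_{ML}$); since these
  inequalities survive averaging across repetitions and athletes, no
  signal can realize those numbers exactly. `sway_recipe()` rejects
  infeasible targets, and `reconcile_path_targets()` projects `PL` into
  the feasible interval (12% interior margin, matching the shape
  designer's attainable range) when building recipes from the group
  tables.
* The squat ellipse areas are published with 0.0 SD while the path-length
  budgets shrink under negative SD shifts, so shifted recipes can demand
  more spread than the remaining path budget supports;
  `recipe_from_group()` probes the designer's maximal attainable area and
  clamps the EA target to 60% of it, leaving calibration headroom.

Defaults that the study description leaves open, chosen once: sampling
rate 100 Hz (typical of commercial sport IMUs), contact at 1.25 s after a
0.4 s flight, sensor mounting tilt 2° (so the re-alignment step is
exercised), gyro noise 0.2 °/s and accelerometer noise 0.03 m/s² —
realistic MEMS magnitudes that keep the round trip within a few percent.
What the generator does **not** emulate: soft-tissue artifact, gyro bias
drift, asynchronous clocks, athlete-to-athlete timing variability within a
session, and any true biomechanics linking the features to each other
beyond the configured correlations. Passing round-trip tests therefore
validate the *measurement-to-feature* chain, not the biological claims.

## Problem sizes and reproducibility

The test suite and the acceptance script use: cohorts of 26/13 (the study
composition) and up to 1000 per group for moment checks; 50 seeds for the
benchmark surrogate; 20 seeds at n = 300 for correlation recovery; 500
trees for importance; 10^4–10^5 points for ellipse coverage; and a handful
of signal recipes spanning the group means ± 1 SD. Every stochastic step
is seeded; `run_pipeline()` derives per-stage seeds deterministically from
the root seed, and identical configurations produce byte-identical
reports.

## Known limitations

* Heading is non-identifiable with 6-axis fusion: if the sensor is mounted
  rotated about its long axis, ML and AP exchange roles; only the static
  calibration convention fixes them.
* The Mahony gains are a fixed compromise; a strongly biased gyro would
  need the integral term retuned (`ki`), and no gyro self-calibration
  beyond it is attempted.
* The goodness-band boundary at exactly $\sqrt{0.5}$ and the reconciled
  path-length targets are conventions imposed where the source material is
  internally inconsistent; both are flagged above.
* Classifier results on the synthetic surrogate overstate real-world
  separability by construction; they validate the pipeline, not the
  screening claim.
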