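---
title: "Classifying postinduction hemodynamic instability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying postinduction hemodynamic instability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemostab)
```

## The model in brief

`hemostab` classifies a patient as *hemodynamically unstable* or *stable*
during anesthesia induction from the shape of the beat-to-beat arterial
blood-pressure trace alone. The underlying view is that instability is not
a threshold crossing but a pattern — how deep and how fast pressure falls,
relative to where it started — and that an expert panel's visual judgement
of that pattern can be learned by a conventional classifier once the trace
is summarized into a fixed feature vector. The pipeline is therefore:
artifact-robust preprocessing onto a common 1-Hz grid, a 98-dimensional
featurization of three induction-relative windows, consensus labelling of
expert votes, and an imbalance-corrected random-forest classifier.

Everything operates in induction-relative time: t = 0 is the administration
of the first induction agent, and all analysis lives on t ∈ [−300, +900] s.

## Preprocessing

Finger-cuff measurements are artifact-prone, so beats are eliminated before
any statistic is computed. A beat is invalid when any of these holds:

| rule | default | meaning |
|---|---|---|
| `pp_min` | 10 mmHg | pulse pressure SAP − DAP below physiologic plausibility |
| `sap_step_max` | 20 mmHg | SAP jump between consecutive beats |
| `dap_context_max` | 25 mmHg | DAP deviating from its 10 enclosing beats |
| `hrs_drift_max` | 35 cm | heart-reference-system height drifted from start |

All rules are evaluated on the **raw** series, which makes flagging
idempotent and order-independent. Three details the rules themselves leave
open, and how this package resolves them:

* *DAP context*: the 10 enclosing values are the 5 preceding plus 5
  following beats, and the deviation is measured from their **median** —
  robust to a run of artifacts inside the context; the mean is available
  via `dap_context_stat = "mean"`. Near the record edges the existing
  neighbours are used; with fewer than 11 beats the rule is skipped.
* *SAP step*: the **later** beat of an offending pair is flagged, on the
  presumption that the earlier beat was the last good value. A genuine
  step artifact therefore also flags the first recovered beat after it,
  which costs a little precision but no recall.
* Records are excluded when more than 4 of the 5 minutes before or after
  induction, or more than 8 of the last 10 minutes, are missing. "Missing"
  needs a coverage semantic for irregular beats: each valid beat covers the
  time to the next valid beat, **capped at 3 s** (`coverage_cap_s`), so a
  handful of sparse beats cannot fake coverage of a long gap.

Remaining valid beats are linearly interpolated to 1 Hz. Interpolation
never extrapolates beyond the first/last valid beat (those samples are
masked) but does bridge internal gaps — records with disqualifying gaps
have already been excluded. A **centered** 45-s moving average follows,
computed over available samples only and truncated at the edges; a
trailing window is selectable (`smooth_align`) for strictly causal use.

## Featurization

Windows: A = [−300, 0) s, B = [0, 300) s, C = [0, 900] s. B is nested in C
deliberately: B captures the acute response, C the full course including
vasopressor rebound.

The default registry enumerates exactly 98 features:

* 3 channels × 3 windows × {min, t_min, max, t_max, mean, var} = 54;
* pulse pressure: 3 windows × {mean, var} = 6;
* mean negative slope per channel over t ∈ [−150, +150] s = 3;
* steepest (most negative) slope per channel in C = 3;
* 1st and 2nd slope deciles per channel in C = 6;
* changes {min, max, mean, var} × 3 channels × {A→B, A→C} = 24;
* pulse-pressure mean changes A→B, A→C = 2.

This enumeration is the package's own construction: it is consistent with
every feature family the method describes and totals 98, but the original
study's authoritative feature list is not public. The registry is
therefore an explicit, serializable object (`feature_registry()`) and
`featurize()` accepts a replacement, so a user holding the authoritative
list can encode it without touching the code. This is the package's
central documented assumption.

Numerical conventions, chosen once and regression-tested:

* Slopes are central differences of the smoothed 1-Hz signal, reported in
  mmHg/min; masked samples propagate (a slope needs its full triple).
* "First and second deciles of the steepest downward slopes" are read as
  the 10th/20th percentiles of the window-C slope distribution (its
  most-negative tail), with the linear-interpolation percentile definition
  (R quantile type 7); a negative-only variant is selectable.
* The mean negative slope averages only strictly negative slope samples;
  a trace with no decline returns 0 and carries a
  `no_negative_slope` attribute rather than NA, keeping vectors finite.
* Extremum times break ties toward the earliest sample; variances are
  n − 1 sample variances.
* Cross-window deltas are anchored at A (the pre-induction baseline), as
  `value(later) − value(A)`, for B and C; B→C deltas are not in the
  default registry.

Two invariants worth knowing: adding a constant to all pressures shifts
only the min/max/mean features and leaves variances, slopes and deltas
unchanged; and `featurize()` is pure — identical signals give identical
vectors.

## Labels and reliability

A subject is unstable when at least 75% of the panel voted unstable,
operationalized as `votes ≥ ceiling(0.75 k)` — with 4 raters, 3/4 and 4/4
qualify, and an exact-75% count (12/16) counts as agreement.

Reliability uses intraclass correlations from the two-way ANOVA
decomposition (subjects × raters), with binary votes fed in as 0/1
numerics — the two-way model is preferred here precisely because strict
categorical agreement indices punish the gray zone between the two labels.
With MSR/MSC/MSE the subject, rater and residual mean squares:

* consistency, single: (MSR − MSE) / (MSR + (k−1) MSE)
* consistency, average: (MSR − MSE) / MSR
* agreement, single: (MSR − MSE) / (MSR + (k−1) MSE + k(MSC − MSE)/n)
* agreement, average: (MSR − MSE) / (MSR + (MSC − MSE)/n)

The random- and mixed-model point estimates coincide; the label records
intent. Degenerate inputs are handled explicitly: a matrix with zero total
variance is a perfectly reproduced constant and returns 1 with a warning,
while a rater voting identically on every subject in both repeat sessions
has an undefined intra-rater ICC and is excluded from the pooled mean
(unweighted across raters) with a warning. Negative estimates are reported
as computed. Intra-rater reliability uses the consistency definition
(single measures, two-way mixed); the absolute-agreement variant is one
argument away. The subpanel check averages votes within each group per
subject and estimates ICC(two-way random, average) on the resulting n × 2
matrix — i.e. groups are averaged first, then correlated. F-based
confidence intervals are available for the consistency forms.

## The classifier harness

70/30 stratified split; min–max scaling fitted on the training set only
(test values may fall outside [0, 1] and are not clipped; a constant
training feature maps to 0 with a warning); SMOTE brings the minority
class to exactly 1:1 by interpolating uniformly on segments between a
minority point and one of its 5 nearest minority neighbours in the scaled
space. Ordering is fixed: **scale, then SMOTE** — synthetic points are
built in the space the classifier sees. During cross-validation SMOTE runs
inside each training fold only, so no synthetic point ever leaks into a
validation fold.

The grid search maximizes mean stratified 5-fold CV AUROC over logistic
regression, k-NN, RBF-SVM and random forests; ties resolve toward the
earlier grid entry, and `default_grid()` is ordered simple-to-complex
within each family to make that a simplicity preference. The original
study's exact grids are unknown, so the defaults are modest and documented
in code. The optimized default classifier is a random forest with 50 trees
and maximum depth 6 (`ranger`, single-threaded for determinism under a
seed). Confusion-matrix metrics use a 0.5 probability cutoff — the
operating point is not prescribed by the method, so it is config-exposed.
AUROC is computed by the mid-rank Mann–Whitney statistic, identical to the
trapezoidal rule with tied scores at mid-rank; the test suite cross-checks
it against both a pairwise oracle and an established ROC package.

Two threshold-based PIH comparators are included: any post-induction MAP
sample below 65 mmHg (one smoothed sample suffices; no duration criterion,
as none is specified for the definition), and a post-induction SAP minimum
below 80% of the window-A mean SAP.

## The synthetic cohort generator

The simulator exists so every stage is testable without clinical data. It
emulates: a ~21% unstable prevalence; unstable patients starting ~11 mmHg
higher systolic (161 vs 150 mmHg baselines); an exponential post-induction
decline `baseline − Δ(1 − exp(−t/τ))` whose magnitude Δ and time constant
τ are class-specific; delayed vasopressor-like rebound bumps (logged as
phenylephrine events); per-beat Gaussian noise; and artifact injection per
elimination rule, at rates chosen so the eliminated-beat fraction of a
default record sits near the ~8–9% median burden the preprocessing rules
are designed for. Ground truth drives generating parameters (not a
threshold on the realized trace), so trace noise and label noise can be
varied independently; simulated experts vote truth-XOR-Bernoulli(flip).

The default *separable* regime (Δ ≈ 65 ± 10 mmHg, τ ∈ [20, 60] s unstable
vs Δ ≈ 10 ± 4 mmHg, τ ∈ [180, 360] s stable) is an end-to-end correctness
check: the full pipeline must reach held-out AUROC ≥ 0.90 across seeds,
and in practice classifies it perfectly. The *overlap* regime draws
overlapping class distributions and is genuinely harder. What the
simulator does **not** reproduce: baroreflex and Windkessel dynamics,
pharmacokinetics, heart-rate coupling, waveform morphology within a beat,
or the gray-zone cases that make real expert labelling hard. Passing the
synthetic suite demonstrates the pipeline's correctness and internal
consistency, not clinical-grade performance on real cohorts — the
published clinical data are not deposited, so clinical AUROC is not
reproducible here.

Two archetypes reproduce the classic discordance between threshold
definitions and instability: a low-baseline slow drifter that is
PIH-positive under MAP < 65 yet stable by construction, and a hypertensive
fast dropper that never crosses 65 mmHg MAP yet is unstable by
construction (`generate_archetype()`).

## Problem sizes and determinism

Every stochastic component takes an explicit seed, and cohorts derive
per-record sub-seeds from the cohort seed, so record, cohort, vote and
pipeline outputs are bit-reproducible. The test suite runs its end-to-end
checks on 100-subject cohorts over 5 seeds and its Monte-Carlo reliability
bands on 200–300 replicates — sizes at which the checked properties are
stable while the whole suite stays fast; the acceptance script uses a
120-subject cohort and 100 artifact-recovery records.

## Storage formats

No storage dialect is prescribed by the method, so the package defines its
own, deliberately plain one: per-record beat CSV (`t, sap, map, dap,
hrs?`) with a JSON sidecar (patient id, induction time, drug events,
optional synthetic ground truth); ratings as a subjects × raters CSV;
features as id + 98 named columns; reports and run manifests as JSON. One
deliberate deviation from strictness: a record shorter than the [−300,
+900] s span loads with a warning rather than an error, because the
missingness check excludes it anyway and a hard error would block
inspection of truncated files.

## Known limitations

* The 98-feature registry is a reconstruction (above); feature-level
  comparisons against the original model are only meaningful under the
  authoritative list.
* MAP is taken from the device stream, never re-derived from SAP/DAP; no
  intra-beat (waveform-contour) or heart-rate features are computed.
* The intra-rater pooling rule (unweighted mean) and the intra-rater ICC
  definition (consistency) are the package's choices where the method
  leaves them unstated; both alternatives are exposed.
* ICC confidence intervals are provided only for the consistency forms;
  agreement-definition intervals would need the noncentral-F approximation
  and are out of scope.
* The classifier harness is deliberately conventional; calibration,
  survival outcomes and external validation are out of scope.
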