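---
title: "Methods: IMU-based functional assessment in vestibulopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU-based functional assessment in vestibulopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imusway)
```

## The problem

Patients with bilateral (BV) or unilateral (UV) vestibulopathy suffer chronic
imbalance that standard reflex tests (video head-impulse, caloric testing) do
not capture at the level of daily-life function. A practical alternative is to
instrument patients with body-worn inertial measurement units (IMUs) while
they perform everyday tasks — dressing, climbing stairs, walking on uneven
ground or in the dark — in a semi-standardized setting, and to derive from the
recorded signals a small set of movement features that separate patient groups
from healthy subjects (HS).

`imusway` implements that analysis as a staged, reusable pipeline:

1. **Signal preprocessing** per trial (one participant × task × sensor).
2. **Feature extraction**: intensity, smoothness and stabilization features.
3. **Task selection**: a dual nonparametric criterion on task duration and
   perceived difficulty reduces the 15-task battery.
4. **Principal component analysis** with permutation-based component
   retention, a cumulative-variance cut, top-loading variable selection and
   bootstrap stability diagnostics.
5. **Discriminant screen**: three-group rank tests on the selected variables.

A synthetic cohort generator with a registry of planted effects makes every
stage testable end to end without clinical recordings.

## Data model and preprocessing

A *trial* is a 6-axis recording — 3D linear acceleration (m/s², ±16 g range
devices) and 3D angular velocity (deg/s) — sampled at 128 Hz from one of five
analysis sensors: head (HE), trunk (TR), sacrum (SA), left and right foot
(LF/RF). Wrist and thigh positions can be ingested but are excluded from
analysis, reflecting the standard finding that they capture task-irrelevant
arm movements.

Preprocessing is fixed in the canonical order **trim, then filter**:

* **Edge trimming** removes the initial and final 5% of samples
  (`floor(0.05·T)` per side), discarding initiation/termination artefacts.
  Trimming on the sample index is equivalent to trimming by time at a fixed
  rate; floor() per side is the package's tie-break, since sub-sample
  rounding is not otherwise determined.
* **Low-pass filtering** applies a 4th-order Butterworth filter with a 6 Hz
  cut-off to each of the six channels. The filter is run forward and backward
  (zero phase): the features below are amplitude statistics, and a one-pass
  filter's group delay would distort signal edges and bias them. The
  effective amplitude response is therefore the squared one-pass magnitude,
  $|H(f)|^2 = 1/(1 + (f/f_c)^{2n})$, which the test-suite checks against
  probe sinusoids. The forward–backward pass is implemented in compiled code
  (direct-form-II-transposed with steady-state initial conditions and
  odd-reflection padding), so constants pass through exactly (DC gain 1) and
  whole cohorts filter in seconds.

The order matters: filtering first would smear start/stop transients into the
retained segment. `preprocess_trial()` enforces the order and marks its
output; `extract_trial_features()` refuses unmarked recordings.

Gravity is *not* removed: the features operate on the filtered raw signals.
Orientation estimation and gravity separation are deliberately out of scope,
and all features are norm-based, which makes them invariant to sensor
orientation (a property the suite verifies under random 3D rotations).

## Movement features

For each preprocessed trial, with $s_{x,y,z}$ the acceleration or angular
velocity components:

* **Intensity** — the elementwise 3D norm
  $s^{3d}_t = \sqrt{s_{x,t}^2 + s_{y,t}^2 + s_{z,t}^2}$, summarized by its
  RMS: `NormLinAcc_RMS` (m/s²) and `NormAngVel_RMS` (deg/s).
* **Smoothness (sway jerkiness)** — the jerk is the time derivative of
  acceleration. The integral form
  $\mathrm{JERK} = \tfrac12 \int_0^T \left(\dot A_x^2 + \dot A_y^2 +
  \dot A_z^2\right) dt$ (m²/s⁵) is exposed as `jerk_scalar()`; the matrix
  feature `JERK_RMS` (m/s³) is the RMS of the 3D jerk-norm series
  (`jerk_rms()`). The duality exists because a scalar integral cannot itself
  have an RMS; defining the matrix feature as the RMS of the jerk-norm time
  series keeps it on an interpretable per-sample scale while the integral
  form is available for comparison with balance literature. Derivatives use
  central differences (one-sided at the ends); integration uses the
  trapezoidal rule. Both discretizations are validated against closed forms
  (ramp: exact; sinusoid: $A^2\omega^2T/4$ within 0.5% at 128 Hz).
* **Stabilization (attenuation coefficients)** —
  $AC_{ij} = (1 - \mathrm{RMS}_j/\mathrm{RMS}_i)\times 100$, computed from
  the RMS of the linear-acceleration norm series of a lower segment $i$
  (denominator) and an upper segment $j$: trunk→head (`AC_TH`), sacrum→head
  (`AC_SH`), sacrum→trunk (`AC_ST`). Positive values mean the upper segment
  attenuates the accelerations of the lower one. The acceleration *norm* is
  used (rather than per-axis RMS), consistent with the other intensity
  features.
* **Task duration** (s), taken from the trial metadata (the full duration
  before trimming).

Per task this yields 5 sensors × 3 parameters + 3 AC + duration = **19
variables**; 8 selected tasks give a 152-column participant × variable
matrix. (The clinical study this design follows reports a 153-variable PCA;
the stated roster arithmetic gives 152, and the package reproduces the roster
as written.) A task a participant rated *impossible* contributes no values —
cells stay missing, never zero.

## Task selection

Perceived difficulty is an ordinal rating (easy = 1 … impossible = 4);
impossible raters contribute the rating but no duration observation. Because
such variables are not plausibly normal (a global Shapiro–Wilk screen is
available as `shapiro_screen()`), all group comparisons are nonparametric:
Kruskal–Wallis across BV/UV/HS, followed — only when the omnibus test is
significant — by Dunn's pooled-rank post-hoc $z$ tests with Holm correction
within the three pairwise comparisons of that task × parameter (the family
matches the per-task reporting convention; no correction is applied across
tasks).

A task enters the analysis set only if **both** duration and difficulty
differ significantly across groups at $\alpha = 0.05$ (two-sided). A forced
list (default: *Walk in the dark*, clinically central to vestibular loss but
prone to under-powered duration differences when darkening goggles are
imperfect) bypasses the statistical rule and is flagged `forced`. If a group
has fewer than two duration observations (most of the group rated the task
impossible), that test is recorded as not computable and the task can enter
only via forcing.

## Principal component analysis

Variables mix m/s², deg/s, percentages and seconds, so the PCA operates on
**z-scored columns** (correlation-matrix PCA); covariance PCA would be
dominated by the units. Missing cells are imputed first — default
`group_median`, which keeps all participants and respects group structure
(`overall_median` and `complete_case` are available). Loadings are
correlation-scaled (eigenvector × component sd; for standardized input these
equal variable–score correlations), and each component's largest-|loading|
entry is made positive, which renders the fit bit-deterministic. Variance
accounted for (VAF) is reported in percent and sums to 100 over all
components.

**Retention** is decided by a permutation test: each of `n_perm` (default
1000) surrogate matrices permutes every column independently, destroying
between-variable correlation while preserving marginals. Component $k$ is
retained if its observed VAF exceeds the 95th percentile of the surrogate VAF
at the same index; testing is sequential and stops at the first failure
(testing marginally at each index with a sequential stop is the package's
choice where the exact interplay is not prescribed; $\alpha$ and `n_perm` are
configurable, and $\alpha \ge 1$ retains everything by definition). Retained
components are then cut to the smallest leading set reaching **50%
cumulative VAF**, dropping trailing components of very low individual
variance.

**Variable selection** keeps, per retained component, the 10% highest
absolute loadings capped at 10 variables; exact ties at the cut are all
included (and logged) rather than broken arbitrarily. The per-component
threshold (smallest retained |loading|) and the union across components are
reported.

**Stability** is assessed by a nonparametric bootstrap (default 1000
iterations): participants are resampled with replacement, stratified by
group; the PCA is refitted; each original component is matched to the
bootstrap component of maximal |Tucker congruence| (greedily from PC1,
without replacement — no Procrustes rotation, since the metrics are
per-component); signs are aligned; and four similarity metrics against the
original loadings are averaged: Pearson $r$, RMS of loading differences,
Tucker's congruence coefficient
$CC = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$, and Cattell's
salient-variable similarity $s$ with hyperplane cut 0.1 (the referenced
methodology's default; loadings with $|l| \le 0.1$ are "hyperplane", and
$s = (c_{++} + c_{--} - c_{+-} - c_{-+})/(n - c_{hh})$). Bootstrap samples
producing a zero-variance column are redrawn and counted. A robust component
shows $r, CC \to 1$ and small RMS.

## Discriminant screen

Each variable in the union is tested with Kruskal–Wallis across the three
groups; Dunn–Holm pairwise tests follow only significant omnibus results.
No correction is applied across the screened variables — a deliberate
faithful-reproduction choice matching per-variable reporting — and group
medians and IQRs accompany each result, with `*`/`**`/`***` stars at
0.05/0.01/0.001.

## The synthetic cohort generator

`simulation_config()` parameterizes a cohort of 3 groups × 20 participants ×
15 tasks × 5 sensors at 128 Hz. Signals are **gravity-free oscillatory
abstractions** of gait: per axis, the sum of the first three harmonics of the
participant's step frequency (1.8 ± 0.1 Hz; harmonic weights 1/0.5/0.25; axis
weights 1/0.6/0.4 with random phases), a 5.2 Hz jitter tone whose relative
amplitude (0.45 for acceleration) degrades smoothness and so controls the
jerk features while staying below the 6 Hz analysis cut-off, and white noise
(5% of amplitude). Base amplitudes fall from feet (3 m/s², 150 deg/s) through
sacrum (1.2, 40) and trunk (0.9, 30) to head (0.7, 25), so baseline
attenuation coefficients are positive, as in upright human movement. Base
task durations span 8–22 s.

Between-subject structure comes from log-normal latent factors: a global
amplitude factor (sd 0.05), a *locomotor* factor (sd 0.25) shared by the foot
sensors across locomotor tasks — the planted common factor that a first
principal component should recover — a per-trial per-sensor wobble (sd 0.10)
driving attenuation-coefficient variability and decorrelating variables
across trials, and participant/trial duration
factors (sd 0.12/0.10). Perceived difficulty follows a latent-normal
threshold model (cut-points 1/2/3, noise sd 0.8): the simplest generator for
a 4-level ordinal response; level 4 (*impossible*) marks the trial
uncompleted and suppresses its signals and duration.

Planted effects are multiplicative entries `(group, task, sensor, parameter,
multiplier)`. `default_paper_scenario()` mirrors the qualitative clinical
picture: reduced foot intensity in patients on uneven ground, the inclined
plane and walking in the dark (BV ×0.65, UV ×0.80), reduced trunk intensity
on the inclined plane, longer BV durations (×1.45; UV ×1.15) on the demanding
tasks, elevated BV head jerk while dressing and sacrum jerk on the wood beam
(×2.0), and latent difficulty shifts (BV +1.4, UV +0.7) on the same tasks —
*Walk in the dark* carries difficulty and intensity effects but deliberately
no duration effect. UV is intermediate in mean with 1.3× inflated variance,
reflecting the heterogeneity of unilateral loss. These constants were chosen
once to give standardized effects of d ≥ 1.5 for BV at n = 20/group, and are
not tuned thereafter. Generation is a pure function of the configuration:
per-participant and per-trial seeds derive deterministically from the master
seed, so any task subset regenerates bit-identically.

What the generator does **not** emulate: biomechanically realistic gait
(stance/swing asymmetry, impacts), gravity and orientation drift, sensor
error models beyond additive white noise, or correlated difficulty/duration
residuals. Passing tests therefore demonstrate that the pipeline recovers
known structure of this statistical shape at clinical sample sizes — not that
it would detect any particular clinical effect.

## Numerical choices and degenerate inputs

* Trimming uses `floor()` per side; a trial must keep ≥ 2 samples.
* Filtering requires cut-off < Nyquist; constants are preserved exactly.
* `rms()` of an empty series, jerk with < 3 samples, a zero lower-segment
  RMS in `attenuation_coefficient()`, zero-variance columns in
  `standardize()`, all-hyperplane inputs to `cattell_s()` and zero vectors in
  `congruence_coefficient()` are errors, not silent values.
* All-identical samples give Kruskal–Wallis p = 1 by convention.
* PCA components are capped at the matrix rank; eigenvalues below
  `1e-12 × max` are dropped.
* Loading-selection ties are all included and logged.
* Every stochastic operation takes an explicit seed; the pipeline derives
  per-stage seeds from its master seed.

## Validation problem sizes

The test-suite validates against closed forms and independent
reimplementations at small scale, and calibrates the stochastic machinery at
the study's sample size (n = 60): 50 pure-noise retention runs (60 × 20,
200 permutations each), a 200-draw bootstrap of a planted one-factor design,
5 full synthetic-cohort recovery runs at n = 20/group, 10 null task-selection
cohorts and 6 null screen cohorts. `scripts/acceptance.R` runs the complete
pipeline once at the full defaults (1000 permutations, 1000 bootstrap
iterations) plus the recovery and null checks, and writes every headline
quantity it computes as JSON.

## Known limitations

* Features are amplitude statistics of filtered raw signals; no
  spatio-temporal gait parameters, frequency-domain features or margins of
  stability.
* The discriminant screen is per-variable; no cross-variable multiplicity
  control and no classifier is fitted.
* Group-median imputation assumes missingness (impossible tasks) is
  group-informative but otherwise ignorable; heavy missingness (> 50% of a
  column) only warns.
* The synthetic generator's simplifications above; conclusions about real
  cohorts require the external-data path (`read_cohort()` on the documented
  on-disk layout).
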