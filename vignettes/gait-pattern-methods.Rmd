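---
title: "Methods: DTW gait phenotyping, forests and clinical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DTW gait phenotyping, forests and clinical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the modelling choices behind `gaitpatterns`: the
dissimilarity and clustering model, the parameter taxonomy, the forest
and classical-statistics layers, what the synthetic generator emulates,
and the numerical conventions that make runs reproducible. It states no
empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## The data model

A gait cycle is one stride of one limb, time-normalized to 201 epochs at
0.5% spacing over 0–100% of the cycle (initial contact at 0%). It
carries up to ten named angle channels in degrees (five sagittal —
mandatory — plus pelvic rotation/obliquity, hip abduction/rotation and
foot progression), three intra-cycle events (opposite toe-off, opposite
initial contact, toe-off, in % of cycle), stride time, stride length and
subject height. The sign convention is fixed: positive means flexion,
dorsiflexion or anterior tilt. Left and right cycles are independent
classification units — gait impairment in the target disorders is often
asymmetric, and treating limbs separately lets asymmetry show up as two
different patterns in one subject.

Phase windows are half-open intervals `[a, b)` in % of cycle derived
from the events: stance `[0, toe_off)` splits into first double support,
single support and second double support; swing is `[toe_off, 100)`.
An epoch at exactly `b` belongs to the next window, so the windows tile
the cycle with no double counting. Terminal swing has no universal
definition; we take the final third of swing (a conventional split) and
keep it in the rule table so it can be changed in one place.

Ingestion of non-normalized captures uses monotone piecewise-cubic
(Fritsch–Carlson) interpolation onto the fixed grid: kinematic traces
are smooth, and a monotone interpolant cannot overshoot at the flexion
peaks the downstream parameters depend on.

## The 43 parameters

Six spatio-temporal parameters (normalized walking speed, cadence and
the four phase percentages) and 37 kinematic parameters are defined by
an explicit rule table: each kinematic parameter is one
(channel, window, operator) triple with operators `value_at`, `min`,
`max`, `mean`, `range`, `time_of_max`, `time_of_min`. The table is
exported as JSON so the mapping is auditable rather than buried in code.
Conventions worth stating:

* **Normalized walking speed** is raw speed divided by subject height,
  in s⁻¹. Height normalization is the simplest of the common choices
  (height, leg length, Froude); the rule table keeps it swappable.
* **Cadence** is steps per second: two steps per stride, so 2 divided by
  stride time.
* `time_of_*` operators report % of the **whole cycle**, not of the
  window, and break ties toward the earliest epoch — deterministic
  timing parameters across platforms.
* "Minimum hip flexion" and "maximum knee flexion" are taken over the
  whole cycle (they operationalize peak hip extension and peak knee
  flexion); parameters naming a phase use exactly that phase window.
  "Mean hip abduction in first double support and single support" uses
  the union window from initial contact to opposite initial contact.
* `value_at` initial contact reads the exact epoch-0 sample; no
  interpolation is needed on the fixed grid.

## DTW dissimilarity and pattern model

Two cycles are compared over the five sagittal channels jointly: the
local cost between epoch *i* of one cycle and epoch *j* of the other is
the Euclidean norm of the difference of the 5-vectors of angles, and the
dissimilarity is the minimal cumulative cost over monotone warping
paths. Choices:

* **Step pattern**: symmetric with weight 2 on diagonal steps, the
  common default of the reference DTW formulation; the first cell also
  carries weight 2. With this weighting the cumulative cost admits
  normalization by n + m, making distances comparable across pairs. The
  symmetric weight-1 pattern and unnormalized costs are available as
  options.
* **No warping window**: all series share the 201-epoch grid, the full
  dynamic program is cheap (compiled in C++), and a band constraint
  would be an extra assumption.
* **No per-channel standardization** by default: all channels are in
  degrees, and rescaling would distort the relative clinical weight of
  joints. Z-scaling is available as an option for sensitivity analyses.

Clustering is unweighted average linkage (UPGMA) on the dissimilarity
matrix — monotone, so the dendrogram has no inversions — and the flat
patterns come from an explicit cut at *k* clusters. The reference
analysis this package operationalizes chose its groups by visual
inspection of the dendrogram; an explicit *k* replaces that subjective
step, with default k = 7 (six interpretable patterns plus an outlier
group in a cohort of the intended size). Clusters are relabeled by
decreasing size (largest = pattern 1, the "most normal" in practice),
size ties broken by formation height; singletons are flagged as
outliers.

## Random-forest layer

All forests use 1000 trees and otherwise the classic Breiman defaults
of the underlying implementation (node size 1 for classification, 5 for
regression, bootstrap of size n with replacement). The mtry grids are
fixed per question — 1/3/6/12 for pattern classification, 1/14/29 for
the mild-vs-healthy contrast, 1/7/14/28 for clinical-feature forests —
and the best mtry is chosen by the reported criterion itself (OOB error,
OOB AUC, or OOB Spearman rho). Importance is Breiman–Cutler permutation
importance (mean decrease in OOB accuracy / increase in OOB MSE),
unscaled.

Two deliberate conventions:

* **OOB, not resubstitution.** Every goodness-of-fit number comes from
  out-of-bag predictions; resubstitution AUC on 1000 trees is trivially
  near 1.
* **Unadjusted marginal effects.** For the mild-vs-healthy forest we
  export the OOB prediction plotted against the raw parameter value
  with a running-mean smoother (window 10% of the data), not partial
  dependence: the question is "what does observing this value tell a
  clinician", not "what is the model's ceteris-paribus response".

Cycles are treated as independent units in the bootstrap, so cycles of
one subject can inform OOB predictions for their sibling cycles. With
strong subject-level signatures this leaks subject identity and inflates
AUCs for targets that are constant within subject — visible on synthetic
data for clinically uncoupled targets like sex. Subject-blocked
resampling would remove the leak but changes the estimand; we keep the
cycle-level convention and note the caveat.

Singleton (outlier) clusters are excluded from pattern-forest training —
a class with one member cannot be OOB-validated — and scored post hoc.

## Classical statistics

* **Z-scores** use the healthy cohort's per-parameter mean and SD; a
  zero healthy SD is an error, never a silent division.
* **Mixed models**: per spatio-temporal parameter, a Gaussian linear
  mixed model with pattern as fixed effect and a random intercept per
  subject, fit by full maximum likelihood (not REML) because the
  likelihood-ratio test compares fixed-effect structures; the LRT is
  chi-squared with (pattern levels − 1) degrees of freedom. Singular
  fits are flagged, not dropped. The null calibration simulation in the
  acceptance suite uses 40 subjects × 8 cycles with pattern varying
  within subject; with patterns constant within few subjects the
  chi-squared asymptotics are anti-conservative — a known small-sample
  property, worth remembering when reading cycle-level p-values.
* **Pattern–clinical models** attach each subject's record to all of
  their cycles (the reference analysis reports cycle-level odds ratios).
  Quantitative features use a linear model with an ANOVA F test; binary
  features a binomial logit model with per-pattern odds ratios against
  the largest (reference) pattern. Complete separation is reported with
  an infinite-OR flag. GMFCS III is pooled with II throughout.
* **Robust regressions** fit parameter ~ age × condition by an MM-type
  estimator (high-breakdown S-estimate refined by a bounded-influence
  M-step) so a handful of aberrant cycles cannot tilt the age slopes;
  CIs are normal-approximation Wald intervals.
* **BCa bootstrap contrasts**: difference of group means with 10,000
  cycle-level resamples by default, stratified by group so both groups
  stay represented; bias correction from the bootstrap CDF at the point
  estimate, acceleration from jackknife skewness. With zero bias
  correction and acceleration the interval reduces to the percentile
  interval (a property the tests exercise). Contrasts are reported in
  raw units and in healthy-SD units.
* **No multiplicity correction** is applied anywhere, matching the
  reporting style of the analysis this package reproduces; treat
  p-values accordingly.

## The synthetic cohort generator

The generator is first-class code, not a fixture: it defines the study
conditions under which the pipeline is validated. The healthy template
is parametric — per channel an offset, low-order harmonics and wrapped
Gaussian bumps — with physiologic landmarks (knee swing peak near 70%
of the cycle, push-off plantarflexion before toe-off at 60%, stance
near 60%). Six pattern signatures are pure operators on the template
parameters (constant offsets, second-harmonic "double hump" on pelvic
tilt, event-locked bumps such as knee flexion at initial contact, peak
delays and attenuations, equinus offsets, and spatio-temporal
multipliers), applied in a fixed order and scaled linearly by a severity
scalar; severity 0 is the identity.

Default magnitudes follow the printed anchors of the reference
analysis where available — knee flexion at initial contact roughly 10°
higher and peak knee flexion several % of cycle later in functional
stages II–III, normalized walking speed declining 0.05 s⁻¹ per year and
cadence 0.046 steps/s per year — and otherwise sit at 2–4 healthy SDs.
The cohort structure mirrors the published one: 26 patients and 33
healthy children, 3–5 selected cycles per limb, 65.4% of patients using
a single pattern, 27% a different pattern per limb, 7.7% two patterns in
one limb, and one extreme stretched-stance outlier cycle to exercise
singleton handling. Noise has three levels: a subject random intercept
per channel (SD 2°), smooth cycle-level noise (low-pass white noise,
SD 1.5°) and event jitter (SD 0.8% plus a subject-level shift); subjects
also carry pace multipliers so the mixed models see genuine
random-intercept variance. Clinical features are drawn per subject from
per-pattern probability tables (stage II–III, polyneuropathy, abnormal
visual evoked potentials and thin corpus callosum concentrated in the
severer patterns; pattern-specific age distributions), and the severity
scalar is higher in stages II–III (1.15 vs 0.9), which is what realizes
the stage-linked contrasts.

What the generator does **not** emulate: marker placement and soft
tissue artifact, kinetic coupling between joints, within-session
fatigue, and the heavy-tailed between-subject variability of real
clinics. Passing the recovery tests therefore shows the pipeline is
correct and well-calibrated under realistic signal-to-noise, not that
real cohorts will separate as cleanly.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; the pipeline spawns
per-stage seeds deterministically from one master seed, so identical
(config, seed, inputs) give byte-identical outputs (a property the
tests assert). The acceptance script checks DTW and linkage against
brute-force oracles (100 tiny pairs; 50 random 12×12 matrices), pattern
recovery as the mean adjusted Rand index over repeated default cohorts
(about 210 patient cycles each), forest behaviour on one default cohort
with 1000 trees, BCa coverage at 500 Gaussian replicates of 200 per
group, and the mixed-model type-I rate at 500 null replicates — sizes
chosen to give stable Monte-Carlo estimates in minutes on one CPU.

## Known limitations

* The dendrogram cut k is a parameter, not an inference; choosing k from
  the data (gap statistics, stability selection) is out of scope.
* Subject leakage in cycle-level OOB validation (above).
* The exchange format stores angles at 4 decimal places; round trips
  are exact at that precision only.
* MM-estimator CIs are asymptotic; for small cohorts a bootstrap of the
  robust fit would be preferable.
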