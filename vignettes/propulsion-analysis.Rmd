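---
title: "Simulating and analyzing handrim wheelchair propulsion across testing modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing handrim wheelchair propulsion across testing modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Handrim wheelchair propulsion is studied overground (OG), on motor-driven
treadmills (TM) and on stationary roller ergometers (WE). Lab modalities are
convenient, but whether their physiological, spatiotemporal and kinetic
outcomes transfer to overground propulsion is an open question — and a fair
comparison requires the external power output and speed to be standardized
across modalities first. `propulsim` implements the full analysis chain of
such a comparison: rolling-resistance estimation and power standardization,
push-by-push kinetics from an instrumented wheel, physiological outcomes
from breath-by-breath spirometry, cross-modality agreement statistics, and
continuous comparison of push-phase profiles with one-dimensional
statistical parametric mapping (SPM).

Because raw data of this kind are rarely deposited, the package includes a
first-class synthetic-data generator with closed-form ground truth. Every
downstream stage is validated against that ground truth, so the whole chain
is testable without any external download.

## The signal generator

`generate_wheel_session()` builds one block of propulsion as the recording
of a measurement wheel: cumulative wheel angle, three force components and
axle torque on a uniform grid (default 200 Hz, a typical rate for this class
of instrumented wheel; the true rate of such devices varies by vendor, so it
is configurable).

**Kinematics are prescribed, not simulated dynamically.** The wheel rotates
at a constant angular velocity during each push, set by the configured
contact angle over the push time, and at a second constant velocity during
recovery, chosen so that the mean forward speed over a cycle equals the
target speed exactly. This keeps every per-push quantity available in
closed form — the point of the generator is oracle construction, not
biomechanical realism.

**Torque templates.** The default push torque is a half-sine of height
$T_{peak}$ over the push phase, chosen because its integrals are analytic:
mean torque $\frac{2}{\pi} T_{peak}$, work per push
$\frac{2}{\pi} T_{peak}\,\theta_c$ with $\theta_c$ the contact angle in
radians. A second, rise-skewed template $u^a (1-u)^b$ (normalized to peak
height, mean $B(a+1,b+1)$ over the mode height) delays the torque build-up
within the push. The skewed shape is how a cohort embodies the reported
treadmill signature — a lower torque profile early in the push phase. A
pure onset *delay* would not work for this purpose: 0–100% time
normalization removes a delay and only shortens the detected push, whereas
a shape difference survives normalization.

**Braking.** Negative work per cycle is realized as a short negative
half-sine torque burst (default 0.12 s) immediately after hand release,
scaled so its work equals the configured `neg_work_per_cycle`.

**Forces.** The tangential (effective) force is $T/r_{rim}$. The total
force magnitude is set to make the push-averaged effective-to-total ratio
equal `fef_target` exactly; the out-of-plane remainder is split evenly over
the two non-tangential axes. This makes the fraction of effective force
(FEF) an exact generator parameter rather than an emergent property.

**Noise** is additive iid Gaussian per force channel and on torque — the
simplest defensible stand-in. The angle channel is noise-free, as encoder
quantization at this resolution is negligible relative to force noise. What
the generator deliberately does *not* emulate: push-to-push variability
within a block, trunk or arm kinematics, fatigue drift, steering
corrections, or autocorrelated sensor noise. Passing tests therefore show
that the *analysis chain* is correct and calibrated, not that it has been
validated against the full messiness of real recordings.

**Grid alignment.** Push onsets are placed half a sample period off the
grid by default. A push lasting a whole number of sample periods then
covers exactly that many strictly positive samples, so push timing
round-trips exactly through detection, and sampled values sit at interval
midpoints, which makes the discrete work sum a midpoint rule.

`generate_coastdown()` produces the two decelerating velocity traces of a
back-and-forth coast-down test, $v(t) = v_0 - (\mu g \pm b)t$ with an
optional constant slope bias $b$, truncated before standstill.
`generate_breath_data()` produces mono-exponential onsets of oxygen uptake
and heart rate toward steady state with a constant respiratory exchange
ratio (RER).

## Kinetics

**Filtering.** `lowpass_filter()` applies a 4th-order Butterworth low-pass
(default 10 Hz) forward and backward, so the pass is zero-phase and the
magnitude response is squared. Each pass uses odd-reflection end padding
*and* steady-state initial conditions (the filter starts as if the edge
value had been applied forever); without the latter, a start-up transient
of several dozen samples leaks into the output. The angle channel is never
filtered — it is an integrated encoder signal, and filtering it would
distort push boundaries.

**Push detection.** Published studies of this kind rarely state their
segmentation rule, so the rule here is explicit and configurable:
candidate regions are maximal runs of strictly positive torque that reach
1 Nm somewhere inside (functionally a hysteresis rule — noise runs never
reach the threshold, and a genuine push is traced out to its zero
crossings, so the measured push time does not depend on the threshold).
Candidates closer than 0.3 s are merged, shorter than 0.1 s dropped, and
boundary samples below 2% of the push's peak torque are trimmed: a
zero-phase filter smears a few near-zero samples beyond the true contact
interval, and the trim removes exactly that leakage (at 2% of peak it
cannot touch genuine half-sine samples, whose smallest sampled value is
about 2.2% of peak at 200 Hz).

**Outcomes.** Per push: push time, cycle time (to the next push start),
contact angle (`angle[end] - angle[start]`), mean/max torque, work and FEF.
Work is discretized as $\sum_i T_i (\theta_{i+1} - \theta_i)$ over the
half-open push interval — a midpoint rule on this grid — which makes the
constant-torque identity $W = \bar{T}\,\theta_c$ exact. FEF defaults to
the ratio of push means (robust near push edges where pointwise ratios
blow up); the pointwise-mean variant is available as `fef_mode =
"mean_of_ratios"` since either reading is defensible.

Per block: power output is the time average of $T\,\omega$ over the span
from the first to the last push start — whole cycles only, because a window
cut mid-cycle biases the average by up to a fraction of one push's work.
Speed is the wheel radius times mean angular velocity over the same span;
angular velocity comes from central differences of the angle, passed
through the same low-pass as the kinetic channels when the signal was
filtered. Negative work per cycle integrates $\min(T\omega, 0)$ per cycle.
Whether braking torque before full release belongs to the push is not
settled in the literature; here everything after the torque zero crossing
counts as recovery, so braking contributes to negative work, not to the
push.

`last_minute_window()` extracts the final 60 s of a block — the
steady-state portion conventionally analyzed — and can mask samples
outside straight-segment annotations for overground circuits with corners;
pushes overlapping masked samples are excluded.

## Standardization of power output

`fit_coastdown()` fits a straight line to each direction's velocity trace
and converts the mean absolute slope to a friction force
$F = m\,\overline{|\dot v|}$. Averaging directions cancels any constant
slope bias exactly. Friction is modeled as constant and independent of
velocity, hence the linear (not quadratic) fit and no air-drag term; the
deceleration model uses translational mass only, which is the level of
detail at which this protocol is reported in the field. $g$ is fixed at
9.81 m/s².

From a fitted profile: `target_power()` gives $P = F v$;
`match_treadmill()` converts a treadmill drag-test force into the pulley
mass making up the difference to the overground friction (clamped at zero
with a warning when drag already exceeds it — a pulling pulley cannot
reduce resistance); `set_ergometer()` returns the simulated friction
coefficient and inertia (the system mass) for a roller ergometer. All three
configurations yield the same target power at the same speed by
construction.

## Physiology

Energy expenditure uses the oxygen energy equivalent
$EE\,[W] = \dot VO_2\,[L/min] \cdot (4.94\,RER + 16.04)\,[kJ/L] \cdot
1000/60$ (the Garby–Åstrup relation, standard in this literature; the
coefficients are arguments, since labs differ). A mean RER outside
[0.7, 1.0] triggers a warning — protein and anaerobic contributions fall
outside the model — but the value is still computed. Gross mechanical
efficiency is $100 \cdot P/EE$. Steady state is asserted, not tested,
matching field practice of analyzing the last minute of a 4-minute block;
a drift check would be easy to add but is deliberately not imposed.
Heart-rate means are missing-aware and participants without heart-rate data
propagate as `NA`, never zero, so cohort-level listwise deletion per
variable works as expected.

## Agreement statistics

`icc_2_1()` implements the two-way random-effects, absolute-agreement,
single-measure intraclass correlation from the mean squares of the
subjects-by-conditions table:

$$ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$$

with F-based confidence intervals (Satterthwaite degrees of freedom, the
McGraw–Wong construction) and the significance test $F = MS_R/MS_E$.
Labels follow the conventional bands (< 0.50 poor, 0.50–0.75 moderate,
0.75–0.90 good, > 0.90 excellent), with `"n.s."` when the ICC is not
significant at $\alpha$ and `"undefined"` when between-subject variance
vanishes (as happens for speed-like outcomes with coefficients of variation
near zero). The test suite checks the implementation against an
independent mean-squares route (a two-way fixed-effects `aov`
decomposition) to 1e-10 and against a Monte-Carlo population value.

`omnibus_test()` screens each condition with Shapiro–Wilk at $\alpha =
0.05$ and runs a repeated-measures ANOVA (via `stats::aov` with an error
stratum) when the screen passes, else a Friedman test. Whether the original
analyses screened raw values or residuals is not stated in the literature
this emulates; condition-wise raw values are the package's documented
choice, and `force =` overrides the selection. `pairwise_tests()` runs
uncorrected paired t-tests with the paired Cohen's d
($\bar d / s_d$) or exact Wilcoxon signed-rank tests with the
matched-pairs rank-biserial correlation $r = (W^+ - W^-)/(W^+ + W^-)$;
no multiplicity correction is applied — an explicit maximize-sensitivity
design choice, not an oversight. Effect-size bands: below 0.2 small,
0.2–0.5 medium, above 0.5 large.

## Continuous analysis (1-D SPM)

`normalize_pushes()` resamples each of the last 20 pushes to 101 nodes over
0–100% of its own push phase by cubic spline interpolation and averages
within participant-condition. `spm_paired_t()` computes the pointwise
paired t-field and performs random-field-theory (RFT) inference:

- smoothness is estimated from the normalized residual gradients,
  $\lambda(q) = \sum_i r_i'(q)^2 / \sum_i r_i(q)^2$, resels per node
  $\sqrt{\lambda / 4\ln 2}$, FWHM the reciprocal of their mean — the
  standard 1-D estimator;
- the search volume is $R = (Q-1)/\mathrm{FWHM}$ resels and the two-sided
  critical threshold $t^*$ solves
  $\alpha/2 = P(T_\nu > u) + R\,\frac{\sqrt{4\ln 2}}{2\pi}
  (1 + u^2/\nu)^{-(\nu-1)/2}$,
  the expected Euler characteristic of a 1-D t-field;
- cluster p-values use the Poisson-clumping approximation with an
  exponential cluster-extent distribution calibrated to the expected
  suprathreshold volume per cluster.

In the maximal-smoothness limit the threshold reduces to the scalar
two-sided critical value, and under a smooth Gaussian null the family-wise
error rate is calibrated (checked at n = 17 over 1000 replicates in the
test suite). Two-sided inference on $|t|$ at $\alpha = 0.05$ is the
default — profile differences can go either way — with both exposed as
parameters. `spm_permutation()` is the nonparametric cross-check: the
sign-flip null of the field maximum (exhaustive up to $2^n \le$ `n_perm`),
with cluster p-values from the permutation cluster-mass null. RFT and
permutation thresholds agree within about 10% for smooth fields, which is
the package's routine consistency check.

Zero-variance nodes are masked (`NA`) with a warning rather than silently
producing infinite t-values; identical inputs yield an empty cluster table.

## The study replica

`run_study()` wires everything together: per participant and modality it
draws generator targets around the per-modality group means and SDs (see
`modality_defaults()` — the emulated study conditions, including a 17-person
cohort, 1.11–1.14 m/s speeds, three 4-minute blocks of which the last
minute is analyzed, and three heart-rate-missing participants), simulates
blocks, runs the kinetics and physiology chain, and produces the
outcome-table report (per-condition mean/SD, pairwise ICC with CI and
label, omnibus, pairwise effect sizes) plus paired SPM comparisons of
torque and total force for every modality pair.

Between-subject draws share a participant random effect across modalities
(fraction 0.8 of the variance). This is what makes cross-modality ICCs
realistic — independent draws would push them toward zero; 0.8 lands the
simulated ICCs in the moderate-to-excellent range reported for such
cohorts. The treadmill condition uses the rise-skewed template
(`shape_rise = 2`, `shape_fall = 1`), which produces the early-push-phase
torque and total-force clusters in OG-vs-TM comparisons. Targets are drawn
once per participant-modality and clamped to physically consistent ranges
(push shorter than cycle, contact angle compatible with the speed target,
FEF in (35, 97)).

Everything stochastic derives from the single `rng_seed`, so a run is
reproducible end to end; `write_study_report()` writes the metrics CSV, the
report CSV, the SPM cluster JSON and a provenance record.

## Numerical choices and problem sizes

Defaults: 200 Hz sampling, 10 Hz/4th-order filter, 1 Nm detection
threshold with 2% boundary trim, 0.1 s/0.3 s minimum push/cycle times,
Q = 101 nodes, last 20 pushes, $\alpha = 0.05$ everywhere, g = 9.81 m/s²,
ICC confidence level 95%. The test and acceptance runs use deliberately
scaled problem sizes chosen to exercise every code path at comfortable
statistical power: 60–240 s blocks, cohorts of 6–17, 20-seed noise
replications, 500-replicate ICC Monte Carlo, 1000-replicate SPM null
calibration, and 1000-permutation sign-flip nulls. These sizes are the
package's own validation design.

## Known limitations

- The generator's prescribed kinematics make every push of a block
  identical up to noise; push-to-push biological variability is absent, so
  within-participant variance downstream comes from measurement noise only.
- RFT cluster p-values are asymptotic approximations; for small cohorts the
  permutation route is the more trustworthy inference and is provided
  alongside.
- The coast-down model ignores wheel rotational inertia (translational mass
  only) and velocity-dependent drag, mirroring the cited field protocol;
  at the speeds involved both corrections are second order.
- Energy-equivalent coefficients assume negligible protein oxidation and a
  true steady state; both are asserted, not verified.
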