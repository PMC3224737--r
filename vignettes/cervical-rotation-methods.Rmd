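---
title: "Methods: helical-axis kinematics of fast cervical rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helical-axis kinematics of fast cervical rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervkin)
```

This vignette is the package's own account of its science: the model behind
each processing stage, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data generator
does and does not emulate.

## The measurement and its model

The test is a fast axial head rotation: a seated subject turns the head "as
fast as possible" to one side and returns at self-paced speed; six rotations
alternate direction. Two 6-DOF receivers (forehead, Th2 spinous process)
report ZYX cardan angles — azimuth, elevation, roll, i.e.
`R = Rz(az) %*% Ry(el) %*% Rx(ro)` — and position at 60 Hz. Only the
orientation channels enter the analysis; only the *outward* rotation is
scored.

Cervical rotation is three-dimensional: axial rotation is accompanied by
conjunct lateral bending and flexion/extension. Describing it by a single
Euler angle would leak this conjunct motion into the primary signal. The
helical (screw) axis description avoids that: any relative orientation
`M = t(M_thorax) %*% M_head` is a single rotation by the helical angle

$$\theta = \arccos\!\left(\frac{\mathrm{tr}(M) - 1}{2}\right)$$

about some axis. One angle captures the full 3-D rotation, and the axis
direction over time tells how much the plane of rotation wanders.

Three signal-level quantities are computed per trial:

* **Helical angle** `theta(t)`, referenced to the first-frame head-on-thorax
  orientation.
* **Angular speed** `|omega|(t)`. Attitude angles cannot be differentiated
  channel-wise (finite rotations do not commute), so the angular velocity is
  read off the skew-symmetric part of `Mdot %*% t(M)` — the kinematic
  relation `Mdot = [omega]x M`. `Mdot` uses central differences (one-sided
  at the ends), and the product is antisymmetrised,
  `A <- (A - t(A)) / 2`, before extracting
  `omega = (A[3,2], A[1,3], A[2,1])`. Central differences are second-order
  accurate and add no smoothing of their own.
* **Finite-helical-axis (FHA) direction.** Axis estimates are unreliable for
  small rotations, so the direction at frame *i* is computed against the
  nearest *earlier* frame *j* whose displacement to *i* is at least 4°
  (`window_deg`). Frames with no such predecessor are undefined. Directions
  carry a sign ambiguity; each is flipped to a non-negative dot product with
  the first defined direction so that downstream dispersion statistics are
  well defined.

### Filtering

Raw channels are low-pass filtered with a 2nd-order Butterworth at 20 Hz
(`cutoff_hz`, `order`). Two choices were open:

* **Application scheme.** The filter runs forward–backward (zero phase,
  doubling the effective order). Rationale: the timing variables (TTP,
  A/D-ratio) must not be phase-shifted; a causal pass would delay the speed
  peak by several milliseconds.
* **What is filtered.** The Euler channels are filtered directly. This is
  legitimate only away from the ±90° elevation singularity, where the
  channels are smooth functions of the orientation; axial rotation keeps
  elevation near zero, and a guard rejects any trial with |elevation| > 80°.

R's `signal::filtfilt` applies no edge treatment, which leaves a transient
at a boundary where the signal is far from zero (the head ends the trial
rotated). `lowpass_filter()` therefore pads each channel by odd reflection
(36 × order samples) before the forward–backward pass; with this the DC
error on constant channels is below 1e-9.

### Resampling

Helical angle and speed are resampled from 60 Hz to 100 Hz (`target_rate_hz`)
with a natural cubic spline, to refine the localisation of the peak and the
threshold crossings. FHA directions stay at the native rate with their
timestamps.

## Segmentation, extrapolation, and the six variables

Peak Speed is the maximum of the 100 Hz speed signal. Start and stop are the
last/first samples at or below 10% of Peak Speed before/after the peak
(`threshold_frac`). For an ideal minimum-jerk profile,
`v(tau) = (A/T) 30 tau^2 (1-tau)^2`, the crossings sit at τ = 0.0866 and
0.9134 (roots of `30 tau^2 (1-tau)^2 = 0.1875`), so the segment spans 82.7%
of the movement time and captures 98.9% of the amplitude. **ROM** is the
helical-angle difference between start and stop on the 100 Hz grid — the
threshold definition makes ROM a mild (~1%) underestimate of the full
amplitude by construction, which is part of the variable's definition, not an
error.

Because the segment starts and stops at non-zero speed, the timing and shape
variables are computed on an *extrapolated* profile that continues each side
to zero:

* **Endpoint placement.** The natural local model of a movement tail is a
  parabola tangent to zero (speed reaches zero with zero slope), under which
  `sqrt(v)` is polynomial in the remaining time — exactly quadratic for a
  minimum-jerk tail. The endpoint is therefore placed where the quadratic
  continuation of `sqrt(v)` (value, slope, curvature at the boundary)
  crosses zero. A quadratic continuation of the *speed itself* was tried
  first and rejected: its discriminant is negative for tails whose curvature
  grows toward zero, which systematically under-extends the profile
  (measured −4% Move Time and SID ≈ 5% on exact minimum-jerk input, against
  a closed-form expectation of < 1%). Fallbacks: linear crossing of the
  `sqrt(v)` slope, then of the raw slope; everything is capped at 0.25 s per
  side, and a side whose speed is *rising* at the boundary falls back to a
  linear ramp with a warning.
* **Extension shape.** A quintic `v(u) = a u³ + b u⁴ + c u⁵` in the distance
  `u` from the endpoint satisfies `v = v' = v'' = 0` at the endpoint
  identically; the three remaining coefficients match speed, slope and
  curvature at the segment boundary. (Matching only five conditions would
  leave a quintic underdetermined; the zero-curvature endpoint condition
  closes the system and is the smoothest choice.) The extension is clipped
  at zero.

From the extrapolated profile: **Move Time** (duration), **TTP** (start to
peak), **NPA** = Peak/Mean speed (1.875 for minimum jerk), **A/D-ratio** =
`TTP / (MoveTime - TTP)` (1 for a symmetric profile).

**SID** fits the minimum-jerk speed profile with duration = Move Time and
amplitude = the time-integral of the extrapolated speed — displacement- and
duration-matched, hence parameter-free and deterministic (no optimiser) —
and reports `100 × RMSE / mean(v_obs)`. Normalising by the mean rather than
the peak keeps SID commensurate across subjects of very different speeds;
`denominator = "peak"` is available.

**CM** stacks the sign-aligned FHA directions observed between start and stop
into a K×3 matrix and reports the SVD condition number σ₁/σ₃. Tightly
clustered axes give a large CM; *small* CM means the rotation plane wandered
(much conjunct movement). At least 3 defined directions are required;
σ₃ < 1e-12 (perfectly coplanar/collinear clouds) returns a 1e6 cap — real
noisy data are full-rank, and published values are O(10).

### Atypical-trial screening

Manual curation of atypical movements is replaced by an automated flag; a
trial is invalid if its peak speed is below 30 °/s, ROM below 10°, the net
axial excursion opposes the instructed direction, or the profile is
multi-peaked (two local maxima within 20% of the maximum separated by a drop
below 50%). Thresholds are arguments. Subject scores are means over the
valid trials of a session, left and right pooled.

## Reliability statistics

For a variable measured in the same subjects on two occasions:

* **ICC**: two-way (subjects × occasions) single-measure ICC. The
  *consistency* form `(MS_S - MS_E) / (MS_S + MS_E)` (k = 2) is the default —
  it ignores a fixed occasion offset; the absolute-agreement form is
  available via `type = "agreement"`. Confidence intervals use the F-based
  two-way interval.
* **SEM** `= SD(test1 - test2) / sqrt(2)` with a χ² interval (the interval
  method is a documented choice; n − 1 df on the differences).
* **CV%** applies the SEM formula to log-transformed values and
  back-transforms: `100 (e^s - 1)`.
* **MD** `= SEM × 1.96 × sqrt(2)` — an exact identity, machine-checked in the
  tests.
* **Heteroscedasticity**: correlation between subject means and absolute
  differences. The product-moment correlation is used (`method = "spearman"`
  available; the two are distinct and the choice is exposed rather than
  guessed).
* **Log-transform rule**: a variable is analysed on the log scale when the
  heteroscedasticity p < 0.05 or pooled |skewness| > 1 (the skewness cutoff
  is a package choice; no standard value exists). The decision is recorded
  in the report row.

## Group analysis

Variables correlated with age (Peak Speed, ROM, NPA) are replaced by
residuals of a pooled (both groups) linear regression on age before group
tests and discriminant analysis. Group comparison is a pooled-variance
two-sided t-test.

LDA uses pooled within-group covariance and **equal priors** — the
classification threshold sits midway between group centroids in discriminant
space. Equal priors is a choice: with 118 NS vs 49 CON, proportional priors
would inflate sensitivity and crush specificity, whereas published
sensitivity/specificity pairs of this test are nearly symmetric.
Leave-one-out cross-validation supplies sensitivity (NS classified NS) and
specificity (CON classified CON); standardized coefficients are raw
coefficients scaled by the pooled within-group SDs. Stepwise selection is
forward entry by Wilks'-lambda partial F (enter 3.84, remove 2.71 — the
conventional defaults), with refitting and LOO evaluation of the final
subset. Note the multiple-candidate subtlety: entry takes the *maximum*
partial F over candidates, so with five null candidates a spurious variable
enters roughly `1 - 0.95^5 ≈ 23%` of the time at the 3.84 threshold; this is
inherent to stepwise selection, not a defect of the implementation.

## O-PLS association model

The response (peak speed) is regressed on 44 questionnaire predictors:
instrument totals (SF-36 subscales, TSK, DASH 1–19), single NDI/DASH items,
and six-level symptom/function questions. Columns (and the response) are
mean-centred and unit-variance scaled; strictly positive columns with
|skewness| > 1 are log-transformed first (an explicit rule standing in for a
software-internal recommendation; applied transforms are recorded).

The fit removes `n_ortho` (default 1) orthogonal components — predictor
variation uncorrelated with the response — then fits a one-component PLS
model. Missing predictor cells are handled by the NIPALS convention: every
dot product runs over present cells only. R²Y is explained variation; Q² is
`1 - PRESS/SS` from `cv_folds = 7` fold-wise refits with a seeded fold
assignment (predictions filter the held-out rows through the training
orthogonal loadings first). VIP for a one-component model is
`sqrt(p) |w_j| / ||w||`, so mean(VIP²) = 1 exactly. VIP confidence intervals
are jack-knife intervals over the fold-deleted refits (the interval method is
a package choice; none is standard). The selection rule: a *model* is
significant if Q² > 0.05; a *predictor* if VIP > 1 with its interval staying
above 0.5.

## The synthetic-data generator

`generate_trial()` emulates the test protocol: a time-warped minimum-jerk
rotation angle (the warp exponent `tau^alpha` moves the speed peak to
`r/(1+r)`, setting the A/D-ratio; the duration is normalised so the realized
peak equals the configured one), an optional band-limited (3–10 Hz)
sinusoidal speed ripple scaled by `ripple_frac` and enveloped to vanish at
the movement ends, a rotation axis that precesses inside a cone of
`axis_wobble_deg` via a smoothed reflected random walk (frozen outside the
movement so the padded ends are stationary), additive Gaussian angle noise,
and 0.5 s stationary padding so segmentation sees sub-threshold speed on
both sides. Head orientation is the axis-angle rotation; the thorax is the
identity plus noise.

`generate_cohort()` draws per-subject latent parameters from group
distributions whose defaults are the published cohort statistics: Peak Speed
348 ± 92 (CON) vs 226 ± 88 (NS) °/s, ROM 61.5 ± 8.3 vs 52.7 ± 9.2°,
A/D-ratio 0.81 ± 0.24 vs 0.74 ± 0.22, ages ~46.5 ± 10 vs 50.5 ± 9 years with
age negatively correlated with ROM (−0.5) and Peak Speed (−0.3) as the real
cohorts show. Ripple and wobble have no published generating values;
they were calibrated once by simulation so that recovered SID and CM fall in
the published range with CM ordered NS > CON (ripple 0.06/0.09,
wobble 12°/5.5° for CON/NS), and the wobble→CM map is re-derivable with
`calibrate_wobble_to_cm()`. Sensor noise is 0.05° — with the 20 Hz
zero-phase filter this leaves a speed-noise floor of a few °/s, consistent
with a test whose 10%-of-peak thresholds worked for subjects rotating at
100 °/s. Two-session cohorts re-draw a between-session component per session
(`between_session_frac = 0.2` of the group variance, chosen to land the
peak-speed SEM near its published ~41 °/s), plus 5% multiplicative
trial-to-trial jitter.

`generate_questionnaire_block()` adds the 44-predictor block: designated
informative items are generated from a Gaussian copula against the subject's
latent peak speed with the *realized sample correlation* forced to
`effect_r` (the noise component is residualized against the latent before
mixing) — without this, sampling noise at n ≈ 118 makes recovery rates
unstable. Six-level items are quantile-discretised to 1..6; instrument totals
stay continuous; ~2% of cells go missing at random.

### What the generator does and does not emulate

It reproduces the location/scale structure of the kinematic variables, the
age confound, test–retest noise, alternating directions, practice-trial
flags, and a questionnaire block with controllable effect sizes. It does
**not** emulate: the true spectral content of human speed ripple (a
sinusoidal stand-in), biomechanically coupled conjunct motion (the axis walk
is statistically, not mechanically, motivated), NPA/SID/CM joint
distributions (these *emerge* from ripple/wobble rather than being
controlled), or pain-related pacing effects. Passing tests therefore show
the pipeline recovers what this generating model encodes — they do not
certify behaviour on real recordings.

## Numerical choices and limitations

* **Problem sizes.** The shipped checks use: a 200-trial recovery sweep over
  100–500 °/s; 1000-replicate type-I calibrations of the t-tests; 50-seed
  O-PLS null calibration at n = 100, p = 44; 30-seed informative-recovery
  runs; and three full-scale (118/49) cohort replicates for the group
  difference (at the published effect size, d ≈ 1.4, the expected p is
  ~1e-10, so a handful of replicates is conclusive).
* **Sampling-resolution floor.** At 60 Hz a 500 °/s rotation of 55° lasts
  ~0.2 s (~12 samples). Central-difference speed underestimates such peaks
  by ~2%, and NPA/SID acquire an upward bias (NPA ≈ 2.0, SID ≈ 7% on clean
  fast trials). Closed-form checks therefore run at 150 °/s, where the floor
  is negligible (NPA 1.882, SID 0.5%); recovery medians over the full range
  stay within their bands.
* **Recovery ground truth.** Ripple and axis wobble *add real angular speed*
  beyond the base profile, so the configured peak is ground truth only for
  perturbation-free trials; the recovery sweep excludes both.
* **Degenerate inputs** are contracts, not crashes: collinear LDA features,
  constant O-PLS columns, sub-threshold rotations for CM, non-decaying
  boundaries in extrapolation and zero-variance reliability inputs each have
  a defined error or warning path, exercised in the tests.
* **Seeds.** Every stochastic routine takes an explicit seed
  (`trial_gen_params`, `cohort_gen_config`, `fit_opls` fold assignment), so
  cohorts, trials and cross-validation splits are exactly reproducible.
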