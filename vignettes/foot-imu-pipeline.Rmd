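---
title: "Reconstructing spatio-temporal running parameters from foot-mounted IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing spatio-temporal running parameters from foot-mounted IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rungait)
```

## The problem

A single inertial measurement unit (IMU) mounted on a running shoe measures
tri-axial specific force and angular rate, typically at 200 Hz. From these
two signals alone the package reconstructs, per stride, six parameters that
running biomechanics cares about:

* **stride time** `t_stride` — time between two consecutive initial
  contacts (IC) of the same foot;
* **ground contact time** `t_gc` — IC to toe off (TO);
* **stride length** `d_stride` — planar displacement of the foot over one
  stride;
* **average stride velocity** `v_stride = d_stride / t_stride`;
* **sole angle** — the sagittal-plane angle between sole and ground at IC;
  negative values indicate a rearfoot strike;
* **range of motion (ROM)** — the frontal-plane (eversion) excursion,
  max minus min, during ground contact.

The central difficulty is that position is two integrations away from
acceleration and orientation one integration away from angular rate, so
sensor noise and bias grow without bound unless the integration is anchored.
The anchor is the **zero-velocity update (ZUPT)**: during midstance (MS) the
foot is momentarily flat on the ground and stationary, so orientation,
velocity and position can be reset once per stride and drift cannot
accumulate across strides.

## Pipeline

### Functional sensor-to-shoe calibration

Each sensor sits on the shoe in an unknown orientation. Two functional
recordings identify it (`calibrate_alignment()`):

1. **quiet stance** — the mean accelerometer vector is gravity in the sensor
   frame and corresponds to the shoe superior axis *z*;
2. **balance board** — the foot rocks about the shoe's medial/lateral axis;
   the first principal axis of the angular-rate samples corresponds to the
   shoe *x* axis. The sign is fixed by requiring a positive projection of
   the dominant rotation sample; `mirror = TRUE` flips the reference for the
   opposite shoe handedness.

The rotation best mapping the two sensor-frame directions onto the two
shoe-frame references is the orthogonal-Procrustes (Wahba) solution,
computed by SVD of the weighted attitude-profile matrix with a determinant
sign correction (`solve_wahba()`). Two non-collinear pairs determine the
rotation uniquely — the third axis is implied by orthogonality — so the
solver must not (and does not) require three pairs. With exact inputs the
recovery is exact to numerical precision; with 1 degree of direction noise
the recovered rotation is within about 2 degrees (both properties are
tested).

### Stride segmentation

All events come from the sagittal-plane angular rate `gyr_x`
(`segment_strides()`):

* the **forward swing** produces one deep negative excursion per stride;
  minima at or below `-swing_min_prominence` (default 3 rad/s) and at least
  0.4 s apart (deepest wins) are the per-stride anchors `n_sp`. A value
  threshold rather than a pure topological prominence is used deliberately:
  the flat-foot midstance produces a long near-zero plateau that is
  topologically prominent between the two positive peaks but has nothing to
  do with swing;
* **IC** is the first dominant local maximum after `n_sp`, shifted by
  `ic_bias_s` (default −10 ms, i.e. 2 samples earlier at 200 Hz). The
  maximum is a biased estimate of the true touchdown; the correction size
  follows the published characterization of this fiducial and its sign
  (earlier) is a configuration parameter because the literature reports the
  bias magnitude without a printed sign;
* **MS** is the argmin of the gyroscope L2 norm within `ms_window_s`
  (default 250 ms, the average stance duration up to 6 m/s; 50 samples at
  200 Hz) after IC, first index on ties;
* **TO** is the first dominant maximum after the *uncorrected* IC maximum
  within `to_window_s` (default 400 ms), shifted by `to_bias_s` (default
  −24 ms, the published overall bias of this fiducial; speed-dependent
  corrections are deliberately not applied because the pipeline targets
  wide 1 m/s speed bins).

"Dominant" means the candidate maximum is the largest sample within
±`peak_window_s` (default 60 ms). Noise-free detections are unchanged by
this rule, but without it realistic gyroscope noise (≈0.01 rad/s) turns
every wiggle on a rising flank into a "first local maximum" and breaks the
cascade. Windows are specified in seconds and scaled by the actual sampling
rate, so non-200 Hz data works; event times are equivariant under
resampling (tested at 400 Hz). Strides with any out-of-range or
mis-ordered event are dropped and reported, never clamped.

### Trajectory: ZUPT strapdown integration

Per stride, on the interval between consecutive midstances
(`compute_stride_trajectory()`):

1. **Orientation.** The attitude quaternion starts at the identity at MS
   (shoe and global frames coincide there, flat foot) and advances by
   `q[n+1] = q[n] ⊗ exp(W[n] / (2 fs))`, where `W[n]` is the pure
   quaternion of the angular-rate sample — scalar-first Hamilton
   convention, renormalized every step. The quaternion exponential handles
   the zero-rotation limit analytically. For the angle parameters the
   segment from IC to MS is additionally integrated *backwards* from the MS
   identity using negated rates, so the orientation at IC is expressed
   relative to the flat-foot attitude; the backward Euler segment is
   concatenated before the forward one. Forward-integrating from the
   backward result's IC attitude returns to the identity at machine
   precision (tested).
2. **Euler angles.** ZYX (yaw–pitch–roll) extraction with the asin argument
   clamped and roll zeroed at gimbal lock. With the shoe frame used here —
   *x* medial/lateral, *y* anterior/posterior, *z* superior — roll is the
   sagittal-plane angle (sole angle) and pitch the frontal-plane angle
   (eversion). The convention is fixed package-wide because the quantity
   definitions depend on it.
3. **Gravity removal.** Each acceleration sample is rotated into the global
   frame by the attitude (the sense is fixed operationally: a static
   flat-foot stream must map to exactly zero after subtracting
   `(0, 0, 9.81)`; this is a tested invariant, because quaternion
   conventions are a classic source of silent sign errors).
4. **Dedrifted double integration.** Velocity is the rectangular cumulative
   sum of gravity-corrected acceleration starting at zero; the linear ramp
   matching the terminal velocity is subtracted, which forces zero velocity
   at *both* midstance endpoints by construction (for any input — also a
   tested invariant); position is the rectangular cumulative sum of the
   dedrifted velocity. Rectangular (first-order) sums are the fidelity
   default; see "Numerical behaviour".

### Parameters and evaluation

Temporal parameters are exact index arithmetic divided by `fs`. Stride
length is the planar `(x, y)` norm of the final position — level running is
assumed, so vertical error is ignored by construction. Sole angle is the
roll component at IC of the concatenated Euler sequence, in degrees; ROM is
max − min of pitch strictly within `[n_ic, n_to]` (the eversion movement
continues after the next midstance, so a wider window would mix strides).

The evaluation module reproduces the comparison machinery used for
multi-position studies: stride-matched Pearson correlations of raw signals
per axis, modality and gait phase (full stride, ground contact, swing;
segments truncated to the shortest length across positions), signed errors
`sensor − gold` (positive = overestimation), the midstance
gravity-violation error `‖acc[n_ms] − (0, 0, 9.81)‖`, and median/IQR/5–95
percentile aggregation with the type-7 (linear interpolation) quantile
definition, recorded in the output metadata. Missing cells (zero variance,
rejected strides) propagate as missing, never as zeros.

## The synthetic cohort

No public recording with ground truth exists for this setting, so the
package ships a rigid-body simulator (`simulate_cohort()`,
`generate_foot_trajectory()`) whose role is to make recovery error
attributable to the algorithm, not the data:

* The foot pose is piecewise-polynomial in time with an **exactly**
  stationary, exactly flat midstance dwell (default 50 ms) in every stride
  — the ZUPT premise holds by construction.
* The sagittal angle is designed in angular-velocity space (piecewise cubic
  Hermite in `ω_x`, hence a C² angle) so that the gyroscope extrema sit at
  prescribed offsets from the true events: the IC-related maximum 10 ms
  after true IC and the TO-related maximum 24 ms after true TO. The
  simulator thereby *emulates the biases* that the segmentation corrects
  for, and noise-free event detection recovers the annotated events
  exactly. Peak amplitudes are solved analytically from the sole-angle and
  periodicity constraints; the design constants (IC gyro peak 3 rad/s
  scaled up for steep landings, swing-dip depth `5 + 0.8·v` rad/s, IC to
  foot-flat 120 ms) are fixed at physiologically plausible values.
* The frontal angle is a quintic Hermite profile whose stance extremes are
  the annotated ROM; the true orientation is `R_y(frontal) · R_x(sagittal)`
  with zero yaw, so ZYX Euler extraction returns the two generator profiles
  exactly and annotations are definitional rather than re-measured.
* Forward progression is a quintic smoothstep per cycle (exact stride
  length between midstances); the swing lift is a C² bump (0.12 m); all
  knot times are snapped to the sample grid.
* Sensors are rigidly mounted with a lever arm and a mounting rotation.
  The accelerometer includes the lever-arm terms
  `ω̇ × r + ω × (ω × r)`; the gyroscope is lever-arm independent
  (bit-identical across mounts), which is the rigid-body property behind
  the observation that inter-position gyroscope correlations exceed
  accelerometer correlations. Default lever arms mimic the four shoe
  positions (cavity, heel, instep, lateral); they are simulator
  parameters, not measurements.
* Artifacts: per-IC damped oscillation on the accelerometer (15 Hz, decay
  10 s⁻¹, direction with a decelerating first lobe so that the shock
  carries net impulse and degrades both the midstance gravity reading and
  the reconstructed trajectory monotonically in amplitude — a designed,
  tested property of the generator), white noise on both modalities, and a
  constant gyroscope bias; all reproducible from a seed, with per-trial
  child seeds spawned from one master seed. Preset impact amplitudes are
  ordered cavity < lateral < heel < instep, mirroring the attachment
  firmness of the four positions; the magnitudes are illustrative
  configuration, not claims about any particular shoe.

What the simulator does **not** emulate: soft-tissue and shoe-upper
deformation (sensors are perfectly rigid between artifacts), slopes or
curved paths (level, straight running only), forefoot-runners' absent
flat-foot phase (the dwell always exists — the ZUPT premise is granted, not
tested), intrinsic sensor miscalibration (inputs are assumed intrinsically
calibrated; scale/non-orthogonality calibration is out of scope), and
sample-to-sample desynchronization between positions. Passing recovery
tests therefore demonstrate algorithmic correctness under the method's own
assumptions, not field accuracy on real shoes.

## Numerical behaviour and known limitations

* **First-order orientation lag.** The attitude recursion uses the
  left-endpoint rate sample, so the integrated attitude lags the true one
  by about half a sample, `ε(t) ≈ (Δt/2)·ω(t)` (≈1.4° at a 500 °/s peak
  and 200 Hz). The lag rotates gravity slightly wrongly before
  subtraction; the resulting stride-length bias is approximately
  `(Δt/2)·g·∫θ dt` over the stride, where `θ` is the sagittal angle — with
  realistic foot-pitch excursions this is **about +1 cm, growing with
  running speed**, and it dominates the noise-free error budget (the
  dedrifted double integration itself is sub-millimetre, which was isolated
  by substituting true orientations). Per-bin median stride-length errors
  on the noise-free cohort are ≈8 mm at 2–3 m/s rising to ≈10–11 mm at
  5–6 m/s, i.e. the fastest bin sits at the edge of a 1 cm recovery
  target. Trapezoidal velocity integration is available
  (`dedrift_integrate` operates on whatever acceleration it is given), but
  the rectangular form is the fidelity default and the orientation
  recursion is the actual bottleneck.
* **Sole-angle boundary error.** Backward integration over [IC, MS] with
  left-endpoint samples carries a boundary error of `ω(t_IC)/(2 fs)`
  (≈0.3° at the defaults) — visible as a small systematic offset in the
  recovery tests.
* **Quantile convention.** All summaries use type-7 quantiles; with other
  conventions IQRs of small cells differ noticeably.
* **Gimbal lock** is resolved by zeroing roll; running kinematics stay far
  from ±90° pitch, so this path only matters for adversarial inputs.
* **Problem sizes.** The shipped tests and the acceptance script use scaled
  cohorts — 2 trials per speed bin and 5 strides per trial (160
  stride-position observations), 100 random rotations for calibration
  recovery, 10⁴ draws for the quantile check — sizes chosen so the entire
  suite re-runs in well under a minute while keeping the Monte-Carlo
  standard errors an order of magnitude below every tolerance they guard.
  The full study-scale design (10/10/15/15 trials per bin) is the
  `simulate_cohort()` default.

## Reproducing the numbers

```{r, eval = FALSE}
# the demo pipeline: simulate -> write -> calibrate -> segment -> integrate
# -> parameters -> evaluate; byte-identical outputs under a fixed seed
out <- run_pipeline("demo", seed = 42)
out$summary

# the headline quantities, recomputed from scratch
# (shell) Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
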