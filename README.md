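# rungait

Spatio-temporal running parameters from foot-mounted inertial sensors.

A single IMU (3-axis accelerometer + 3-axis gyroscope, nominally 200 Hz)
mounted on a running shoe is enough to reconstruct, per stride, the six
parameters endurance-running biomechanics works with: stride time, ground
contact time, stride length, average stride velocity, the sagittal sole
angle at initial contact (negative = rearfoot strike) and the
frontal-plane range of motion (eversion) during ground contact. `rungait`
implements the complete chain for researchers working with shoe-mounted
IMUs, plus the evaluation machinery needed to compare sensor mounting
positions, and a rigid-body simulator that supplies ground truth where no
public motion-capture dataset exists.

## The method

* **Functional calibration.** Two short recordings — quiet stance
  (gravity ↦ shoe axis *z*) and balance-board rocking (dominant gyroscope
  principal axis ↦ shoe axis *x*) — give two vector pairs; the
  sensor-to-shoe rotation is the Wahba/orthogonal-Procrustes solution
  `R = U diag(1, 1, det(UVᵀ)) Vᵀ` from the SVD of the attitude-profile
  matrix `B = Σ wᵢ vᵢ^shoe (vᵢ^sensor)ᵀ`.
* **Stride segmentation** on the sagittal angular rate `ω_x`: the forward
  swing minimum anchors each stride; IC and TO are bias-corrected local
  maxima (−10 ms and −24 ms by default); midstance (MS) is
  `argmin ‖ω‖₂` within 250 ms of IC.
* **ZUPT strapdown integration.** Per stride, from midstance to midstance:
  quaternion attitude propagation `q[n+1] = q[n] ⊗ exp(W[n]/(2 f_s))`
  initialized at the identity (flat, stationary foot), gravity removal
  `a_gc[n] = q[n] ⊗ a[n] ⊗ q[n]⁻¹ − (0, 0, 9.81)`, rectangular
  double integration with a linear velocity dedrift that enforces zero
  velocity at both midstances; a quaternion backward pass covers [IC, MS]
  for the angle parameters. Then
  `t_stride = (n_IC' − n_IC)/f_s`, `t_gc = (n_TO − n_IC)/f_s`,
  `d_stride = √(s_x² + s_y²)`, `v_stride = d_stride/t_stride`.
* **Evaluation.** Stride-matched Pearson correlations of raw signals per
  axis/modality/gait-phase between positions, signed errors
  `E = P_sensor − P_gold`, the midstance gravity-violation error
  `E_a = ‖a[n_MS] − (0, 0, 9.81)‖₂`, and median/IQR summaries by 1 m/s
  speed bin (2–6 m/s).
* **Simulator.** Piecewise-polynomial rigid-body foot trajectories with an
  exactly stationary flat-foot dwell per stride, four lever-arm-offset
  sensor mounts with arbitrary mounting rotations, and seed-reproducible
  attachment artifacts (impact shock, white noise, gyro bias). Ground
  truth (events and all six parameters) is annotated definitionally.

The methods vignette (`vignettes/foot-imu-pipeline.Rmd`) documents the
conventions, the generator design and the numerical error budget.

## Worked example

Simulate a 3 m/s rearfoot stride train, calibrate the cavity sensor from
its functional recordings, and analyze:

```r
library(rungait)

m  <- gait_model(t_stride = 0.75, duty = 0.36, d_stride = 2.25,
                 sole_angle_deg = -10, rom_deg = 9)
tr <- generate_foot_trajectory(m, n_strides = 5, fs = 200)

mounts <- default_mounts()
stream <- project_to_sensor(tr, mounts$cavity, position_label = "cavity")
cal    <- simulate_calibration_recordings(mounts$cavity)
R      <- calibrate_alignment(cal$static, cal$board)
shoe   <- align_stream(stream, R)
analyze_recording(shoe)
```

```
 stride_id t_stride_s t_gc_s d_stride_m v_stride_mps sole_angle_deg rom_deg
         1       0.75   0.27       2.26        3.013         -10.32   9.135
         2       0.75   0.27       2.26        3.013         -10.32   9.135
         ...
```

Reading: every stride of the constant-speed train is recovered with stride
time exact to the sample (truth 0.75 s), ground contact time exact (truth
0.27 s after grid snapping), stride length 2.26 m against a true 2.25 m
(the ≈1 cm overestimate is the documented first-order integration bias),
sole angle −10.3° against −10° (rearfoot, sign correct) and range of
motion 9.14° against 9°. The same call works on real CSV recordings loaded
with `read_imu_csv()`.

The full demo pipeline (simulate → write dataset → calibrate → segment →
integrate → parameters → evaluate), deterministic byte-for-byte under a
fixed seed:

```r
out <- run_pipeline("demo", seed = 42)
out$summary      # median/IQR of the six parameter errors per position/bin
```

A thin command-line wrapper over the same functions is installed with the
package: `Rscript $(Rscript -e 'cat(system.file("scripts/rungait.R", package="rungait"))') run --out demo --seed 42`.

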