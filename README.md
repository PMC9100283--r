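# skelmerge

Markerless human motion capture with a single RGB-D sensor degrades whenever
a joint is hidden from the camera by the subject's own body: the tracker
falls back to guessing, and the guessed joint can land hundreds of
millimeters from the truth. `skelmerge` merges the skeleton streams of
several sensors surrounding the subject into one accurate 16-joint track,
for researchers in movement science, rehabilitation and human-computer
interaction who need millimeter-scale joint positions without a marker-based
motion-capture system.

## The method

Given per-sensor skeleton streams (joint positions in mm with per-joint
confidence levels `medium` / `low` / `none`), the pipeline is:

1. **Extrinsic calibration.** Each sensor tracks the centroid of a sphere of
   known radius R (RANSAC fit of the sphere surface to the segmented point
   cloud). Frames missing from any sensor are discarded; the surviving
   correspondences `C_p` (target sensor) and `C_M` (master sensor) give the
   rigid transform minimizing

       E(R, T) = Σᵢ ‖ C_M,i − (R C_p,i + T) ‖²

   via the SVD of the cross-covariance Σᵢ (C_M,i − ĈM)(C_p,i − Ĉp)ᵀ, with a
   determinant sign correction so no reflection can be returned. A
   four-marker plate then maps everything into a user-defined global frame.
2. **Misorientation correction.** Trackers sometimes exchange a joint pair's
   left/right labels. For each pair, the cross-sensor reference position is
   the mean of the `medium`-confidence candidates (falling back to `low`);
   a sensor whose right joint is farther from the right reference than its
   left joint is (`D_correct > D_wrong`) has the pair's labels swapped back.
3. **DBSCAN merging.** Per joint, the sensor candidates plus two auxiliary
   candidates — the reference position and the previous merged position —
   are clustered with DBSCAN (searching area ε, minimum neighborhood size
   N_c = 1). The largest cluster wins and the merged position is the
   centroid of its *sensor* members only, so occlusion outliers in smaller
   clusters never contaminate the estimate.
4. **Kalman tracking.** A per-joint constant-position Kalman filter
   (A = H = I, Q = 0.01, R = 1.0) smooths residual tremble; the one-step
   prediction is the tracked output.

Pipeline variants `A1` (plain averaging), `A2` (A1 + correction), `A3`
(correction + DBSCAN), `A4` (A3 + previous-position smoothing candidate) and
`A5` (A4 + Kalman) are selectable for component-wise comparison.

A synthetic module generates ground-truth gesture motion (hands up/down,
jump, squat, lunge, walking, standing sway) with exactly constant bone
lengths, and corrupts it with per-sensor jitter, occlusion-driven outliers,
left/right swaps, confidence degradation and dropouts — so the whole
pipeline is testable without hardware.

## Worked example

```r
library(skelmerge)

spec   <- gesture_spec("random_movement", n_frames = 500, seed = 42)
truth  <- generate_gesture(spec)
stream <- observe(truth, sensor_rig(4), noise_model(seed = 42))

merged <- fuse_sequence(stream, fusion_config("A5", eps_mm = 100))
head(merged, 4)
#>   frame_index joint        x_mm  y_mm  z_mm status n_contributing
#> 1           0 pelvis      -2.58  5.46  961. merged              4
#> 2           0 spine_naval  2.01 -9.72 1108. merged              4
#> 3           0 neck         9.21 -7.75 1405. merged              4
#> 4           0 head        -3.12  4.61 1553. merged              2

region_summary(joint_errors(merged, truth))
#>   region     ae_mm std_mm rmse_mm     n
#> 1 torso       4.55   1.93    4.94  4000
#> 2 upper_limb  4.72   2.51    5.35  2000
#> 3 lower_limb  2.59   1.39    2.94  2000
```

`ae_mm` is the average Euclidean joint-position error against the ground
truth, pooled per body region over all frames; `std_mm` and `rmse_mm` are
its standard deviation and root mean square. Comparing pipeline variants on
the same streams shows what each stage buys (average error in mm):

```r
compare_variants(stream, truth, variants = c("A1", "A3", "A4", "A5"))
#>   variant torso upper_limb lower_limb
#> 1 A1      25.7       33.9       26.1        # outliers poison the mean
#> 2 A3       9.57       9.84       9.67       # DBSCAN rejects them
#> 3 A4       9.58       9.87       9.68       # + one-frame smoothing
#> 4 A5       4.55       4.72       2.59       # + Kalman tracking
```

and accuracy improves with the number of sensors merged (every size-k
sensor subset is fused and the error averaged across subsets; k = 1 scores
raw single-sensor streams):

```r
sweep_sensors(stream, truth, fusion_config("A5"))
#>   n_sensors n_combinations lower_limb torso upper_limb
#> 1         1              4      34.6  34.0       43.2
#> 2         2              6       5.41  6.27       7.57
#> 3         3              4       3.23  4.89       5.25
#> 4         4              1       2.59  4.55       4.72
```

`autoplot()` methods draw these tables, and `plot_skeleton()` draws a pose.
A command-line interface wrapping the same functions (subcommands
`simulate`, `calibrate-extrinsic`, `calibrate-marker`, `fuse`, `evaluate`,
`sweep`) is installed at `system.file("cli", "skelmerge.R", package =
"skelmerge")`.

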