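---
title: "Multi-sensor skeleton fusion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sensor skeleton fusion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelmerge)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic benchmark does
and does not emulate, and the decisions taken where the design was
genuinely open.

## The problem

A single RGB-D body tracker degrades unpredictably under self-occlusion:
joints hidden behind the body are *estimated* rather than tracked (reported
with `low` confidence) and can be displaced by hundreds of millimeters.
Surrounding the subject with several sensors makes every joint visible to
someone — but raises the question of how to merge several partially wrong
skeletons into one good one. `skelmerge` implements a merging pipeline
whose core idea is that the *density* of candidate positions identifies the
inliers: candidates that agree cluster tightly, occlusion outliers are
scattered.

## Calibration

**Sphere trajectories.** Each sensor reports the 3D centroid of a tracked
calibration sphere (radius a config value; 240 mm in the benchmark) over
synchronized frames. `ransac_sphere_center()` robustifies the centroid:
sphere hypotheses through 4 random points are rejected unless the fitted
radius is within `radius_tol_mm` (default 20) of the known radius, inliers
are points within `inlier_tol_mm` (default 10) of the surface, and the best
hypothesis is refined by fixed-radius Gauss-Newton least squares on its
inlier set. The minimal sample of 4 and both tolerances are package
choices; the defaults (200 iterations) recover a clean 200-point sphere
center to ~0.2 mm under 20% box contamination.

**Rigid registration.** Frames missed by any sensor are filtered out
(`build_trajectories()`); at least 3 correspondences are required, and the
benchmark uses 1000. `estimate_rigid_transform()` minimizes
$\sum_i \lVert C_{M,i} - (R\,C_{p,i} + T)\rVert^2$ by the SVD of the
cross-covariance of the centered point sets. Two numerical choices are
deliberate:

* the rotation is $R = U\,\mathrm{diag}(1,1,d)\,V^\top$ with
  $d = \mathrm{sign}(\det UV^\top)$ — without the sign correction, noisy
  near-planar trajectories can return a reflection ($\det R = -1$), which a
  rigid transform must never be;
* the translation is $T = \hat C_M - R\,\hat C_p$, i.e. applied to the
  *rotated* target centroid. This is the unique least-squares minimizer;
  subtracting unrotated centroids is not.

Collinear trajectories leave the rotation about the line unidentifiable;
the fit raises a rank-deficiency error (second singular value below
1e-9 of the first) rather than returning an arbitrary rotation.

**Marker plate.** The global frame comes from four coplanar fiducial
centroids: x runs from marker 1 to marker 2, a provisional y from marker 1
to marker 0, z is their normalized cross product with its sign fixed by an
`up_hint` so z points floor-to-ceiling, and y is re-orthogonalized as
z × x because measured marker vectors are never exactly perpendicular.
Marker 1 is the origin. The axis direction convention (2−1 rather than
1−2) and the default `up_hint` (camera-up, `c(0, -1, 0)` in sensor
coordinates) are configurable.

## Misorientation correction

Per mirrored pair (shoulders, elbows, wrists, hips, knees, ankles), the
cross-sensor reference position of a joint is the mean of its
`medium`-confidence candidates, falling back to the `low` ones. A sensor
observing both pair members is flagged when the distance from the right
reference to its right joint exceeds the distance to its left joint, and
its labels (positions and confidences) are swapped back. Choices:

* **Per-sensor decisions.** Each sensor's pair is checked and corrected
  independently; the reference is global across sensors.
* **Ties.** `d_correct == d_wrong` (e.g. coincident targets) does *not*
  swap: swapping on ties would oscillate between repeated applications.
  With this rule the correction is idempotent (a property test asserts it).
* **Correctability.** The reference is only informative when fewer than
  half the sensors are swapped at `medium` confidence — with exactly half,
  the reference sits at the pair midpoint and the rule is undecidable. In
  practice misoriented joints are occlusion-time estimates and arrive with
  `low` confidence, which is how the simulator plants them; the
  10,000-frame recovery check (1–2 of 4 sensors swapped, 300 mm separation,
  5 mm jitter) corrects ≥ 99%.

## DBSCAN merging

The clusterer is written from first principles (it is the core of the
merging step, not an off-the-shelf dependency) with two semantics fixed by
the algorithm it implements: the neighbor test is the **closed** inequality
`distance ≤ ε`, and a point's neighborhood includes itself — so with
`N_c = 1` every point is core, nothing is noise, and the clusters are
exactly the connected components of the ε-neighborhood graph. A 500-instance
randomized test checks label-permutation equality against a brute-force
connectivity oracle. One transcription choice: the published pseudocode
this follows scans the *seed* point again inside the expansion loop, which
would prevent clusters from growing; the expansion scans the dequeued
neighbor, i.e. standard queue-based DBSCAN. Points labeled noise early are
not reclaimed as border points later (faithful to the queue formulation;
irrelevant at `N_c = 1`).

Per joint, the candidate set is the sensor candidates (confidence ≠ `none`)
plus up to two auxiliary candidates: the reference position — realizing
"give more weight to high-confidence candidates" as *candidate inclusion*,
the only mechanism concretely describable, rather than multiplicative
weighting — and, for variants A4/A5, the previous merged position, which
smooths single-frame drops. Auxiliary candidates count toward cluster size
but are excluded from the merged centroid, so the output stays inside the
range of actually observed positions. The winning cluster is the largest;
ties prefer (in order) the cluster containing the reference, the one
containing the previous position, the one whose centroid is nearest the
previous position, then the lowest cluster id — the trust hierarchy of the
auxiliary candidates. If the winner contains no sensor candidate the
previous position is carried forward (`predicted_only`); after
`max_predict_frames` (default 30) consecutive carries the joint is reported
`missing` rather than extrapolated forever.

The searching area ε defaults to 100 mm (the best-performing value; the
evaluation module sweeps 50/100/150/200 mm). Configuration files accept ε
with an explicit `cm` or `mm` suffix; internally everything is millimeters.
`N_c` is fixed at 1 by default. The previous position fed to merging is the
raw previous merged centroid, not the Kalman output — the smoothing
candidate should reflect what was *observed*, not what was filtered; this
is configurable in principle via the engine state.

## Kalman tracking

Each joint runs an independent constant-position filter with
$A = H = I_3$, isotropic $Q = q I$, $R = r I$, $q = 0.01$, $r = 1.0$.
Prediction $\tilde X_t = \hat X_{t-1}$, $\tilde P_t = P_{t-1} + Q$; with a
measurement, gain $K = \tilde P(\tilde P + R)^{-1}$ and the usual update.
The tracked output is the *prediction* $\tilde X_t$; the filter is
initialized at the first merged measurement with $P_0 = I$ (mm² scale), so
the first tracked position equals that measurement exactly. The
steady-state per-axis gain has the closed form
$K_\infty = M/(M+r)$, $M = (q + \sqrt{q^2 + 4qr})/2 \approx 0.09512$ for
the default $q, r$, which both a unit test and the acceptance script verify
against the iterated Riccati recursion.

**Known limitation.** A gain of 0.095 at 30 fps means the filter trusts
each new measurement ~10%: tracking a joint moving at speed $v$ lags by
roughly $v/K_\infty$ per frame-interval, i.e. ≈ 0.35 mm of lag per mm/s of
joint speed. The constant-position model therefore *helps* (it averages
jitter) only while joints move slowly — below roughly 30 mm/s with the
benchmark's noise levels — and *hurts* fast limbs. This is an inherent
property of the published parameterization, kept as-is; the variant
comparison below is run on the standing-sway gesture where the assumption
holds, and users tracking fast motion should raise `q` or disable the
filter (variant A4).

## The synthetic benchmark

`generate_gesture()` produces analytic kinematic templates, not
biomechanical simulations: their job is to exercise the pipeline under
motion with exactly constant bone lengths (legs use exact two-link inverse
kinematics; arms are rotated rigidly about the shoulder; the torso
translates rigidly). Six gestures mirror a typical capture protocol: hands
up/down (sinusoidal arm elevation), jump (whole-body vertical excursion),
squat (pelvis descent, fixed ankles), lunge (split stance with forward-down
oscillation), walking (in-place shuffling with alternating leg swings —
capture areas are a few meters, so the default is bounded oscillation; a
`speed_mm_s` parameter gives constant-velocity translation instead) and
random movement (seeded smooth sway in a standing pose). Default
amplitudes/periods are deliberately gentle (peak joint speeds ~50–100 mm/s)
so the Kalman stage operates in its assumed near-stationary regime; they
were chosen once, from the lag analysis above, as the package's benchmark
conditions.

`observe()` corrupts ground truth per sensor with the error structure the
pipeline assumes:

| parameter | default | meaning |
|---|---|---|
| `jitter_sigma_mm` | 5 | per-axis Gaussian jitter, visible joints |
| `occluded_jitter_sigma_mm` | 15 | jitter for occluded (estimated) joints |
| `outlier_prob` | 0.15 | occluded joints get an outlier displacement |
| `outlier_scale_mm` | 300 | half-normal magnitude of that displacement |
| `swap_prob` | 0.02 | per pair/frame/sensor left-right swap (demotes to `low`) |
| `dropout_prob` | 0.02 | observation lost (`none`, `NA` position) |
| `occlusion_angle_deg` | 90 | facing-angle threshold for occlusion |

Occlusion is geometric: a joint is occluded for a sensor when the angle
between the subject's facing direction (+x) and the joint-to-sensor ray
exceeds the threshold — a cheap stand-in for depth-shadowing that
reproduces the phenomenology (back-facing sensors produce low-confidence,
outlier-prone estimates). What the simulator does **not** model: pixel-level
body tracking, bone-length errors in the tracker itself, correlated noise
across joints, multiple subjects, sensor interference. Passing tests
therefore demonstrate that the pipeline recovers planted structure under
its own error model, not performance on any particular hardware.

The default benchmark for the structural checks is 4 sensors (azimuths
45°/135°/225°/315°, 2.5 m radius), 6 gestures × 1000 frames at 30 Hz, 20
seeds for the test suite (5 seeds × 6 gestures in the faster acceptance
script, and 10 seeds for the variant comparison there); these sizes are the
package's benchmark definition.

## Evaluation

`joint_errors()` scores per-joint Euclidean distance (mm) between tracks
aligned on `frame_index`; pairs missing or non-finite on either side are
excluded pairwise and counted. Region aggregates pool per-frame errors
within torso (8 joints), upper limb (4) and lower limb (4): the average
error (AE), its standard deviation (STD — population formula by default,
sample optional, since the estimator is a convention) and RMSE are all
reported because field usage alternates between AE and RMSE. The
sensor-count sweep averages AE/STD over *all* subsets of each size
(4/6/4/1 combinations for 1–4 of 4 sensors); size 1 scores raw streams,
since merging one sensor is a no-op.

## Numerical and engineering notes

* The per-frame engine (arrangement, clustering, merging, tracking) is
  C++ (Rcpp): a sensor-subset sweep runs ~29 million single-joint merges,
  which the compiled engine does in seconds. The exported R functions
  (`dbscan_cluster()`, `merge_joint()`, `arrange_frame()`, `fuse_frame()`)
  call the same compiled code, so unit tests exercise the production path;
  `kalman_step()` is additionally implemented in plain R in full 3×3
  matrix form, and a test asserts the engine's A5 output equals an R-level
  Kalman pass over the A4 output to 1e-9.
* With isotropic initialization the Kalman covariance stays a scalar
  multiple of I; the engine exploits this, the R form does not — their
  agreement is part of the test above.
* Streams are validated on read: mandatory header, literal confidence
  strings, finite positions unless confidence is `none`, duplicate
  (frame, sensor, joint) rejection, and per-sensor monotone frame indices
  (frames are synchronized by hardware counter; no timestamp resampling is
  attempted).
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so benchmarks, tests and the acceptance script are bit-reproducible.

## Scope and limitations

Single subject only; no anthropometric (bone-length / joint-angle)
constraints; no confidence-weighted averaging beyond the reference-candidate
mechanism; the 17th joint (`spine_chest`) is available via
`include_spine_chest` for trackers that report the spine as two joints, but
the canonical skeleton is the 16-joint set whose region partition (8/4/4)
is arithmetically consistent. Sensor SDK interfacing, color segmentation
and fiducial detection are upstream of this package: it consumes their
outputs (centroid trajectories, marker centroids, skeleton streams).
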