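---
title: "Propagating model-calibration uncertainty through inverse gait analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating model-calibration uncertainty through inverse gait analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Constrained inverse kinematics fits a kinematic model — a tree of rigid
segments connected by low-degree-of-freedom joints — to measured marker
trajectories. The fit is only as good as the model's calibration: the
registered position of each marker in its segment's frame, and the
segment dimensions obtained by scaling a generic model to the subject.
Both are uncertain at the centimetre level in practice, because placing
physical markers on anatomical landmarks, and registering their virtual
counterparts on a model, is not a precise task. `mocapuq` treats these two
calibration inputs as random quantities, propagates them through the full
inverse-analysis chain by Monte Carlo, and reports the induced spread in
joint angles, moments, powers and downstream clinical classifications.
The central idea is a *population of equally plausible models*: each
member fits the data essentially as well as the original, so no statistic
of the data can prefer one over another, and the honest result of the
analysis is the range over the population rather than any single curve.

## The model

A `link_segment_model` is a tree rooted at a free-floating base (the
pelvis in the shipped gait model). Each segment carries a joint to its
parent (`free` = 3 translations + 3 ordered axis rotations, `ball`,
`universal`, or `pin`), mass, centre of mass, inertia about the com, and
registered markers with IK weights. Frames are right-handed, x forward, y
up, z to the subject's right; rotations are radians internally and degrees
only at I/O and reporting boundaries. Joint rotations compose
intrinsically about axes fixed in the parent frame, so a ball hip with
axes z, x, y is the familiar flexion/adduction/rotation sequence.
Free joints are supported at the root only; every other joint is 1–3
rotational dof, which is what keeps the model kinematically constrained —
the point of the method, since unconstrained (free-segment) fits can hide
registration error by overfitting.

The default fixture (`default_gait_model()`) is the smallest model that
exhibits all nine reported peak metrics: pelvis + thigh/shank/foot per
leg, 16 coordinates, 14 markers, total mass 83.5 kg with head–arms–trunk
lumped into the pelvis segment (anthropometric fractions: thigh 10%,
shank 4.65%, foot 1.45% per leg). Coordinate bounds default to ±π
(rotations) and ±5 m (translations) and are overridable per joint.

## The pipeline

**Inverse kinematics.** Each frame solves
min<sub>q</sub> Σᵢ wᵢ‖mᵢ(q) − oᵢ‖² subject to coordinate bounds, by
Levenberg–Marquardt with an analytic geometric Jacobian
(∂m/∂q = a × (m − p) for a rotation about ground-frame axis a through
joint centre p; the axis itself for translations) and projection of steps
onto the bound box. Convergence: gradient ∞-norm < 1e-10 or step norm
< 1e-12, 200-iteration cap (a convergence failure is an error, not a
silent result). Trajectories solve frame by frame warm-started from the
previous solution (neutral pose at frame 0), which makes the solve
deterministic and invariant to batching. Markers with missing samples are
dropped from that frame's objective; a frame with fewer than 3
non-collinear usable markers is an error. Per-marker errors and per-frame
RMSE are retained in the solution object.

**Filtering and differentiation.** Rotational coordinates are unwrapped,
then every coordinate is filtered by a 4th-order zero-phase Butterworth
low-pass (forward–backward, effective order 8, default cutoff 6 Hz — the
conventional gait-kinematics choice). The two passes are assembled from
`signal::filter` with odd end-reflection padding and step-steady-state
initial conditions, so DC gain is exactly 1 and a constant signal passes
unchanged to machine precision. Velocities use central differences
(one-sided at the ends); accelerations apply the same operator twice. On
band-limited signals below half the cutoff the filtered derivative tracks
the analytic one within 2% away from the boundary frames; the first/last
~15 frames of a trial carry visible end effects, as in any zero-phase
off-line pipeline.

**Inverse dynamics.** A recursive Newton–Euler evaluation: the outward
pass propagates angular velocity/acceleration and linear acceleration
down the tree (including the axis-rate terms of multi-axis joints); the
inward pass accumulates each segment's inertial wrench, gravity and any
applied external loads, and projects the transmitted joint wrench onto
each coordinate's instantaneous axis. The free base cannot be actuated,
so its six generalized forces are the residual wrench needed to realize
the motion; it is returned alongside the joint moments, never absorbed.
Sign convention: a positive moment drives its coordinate in the positive
direction (flexion coordinates are positive in flexion). External loads
are linearly resampled onto the kinematic time base; measured force-plate
channels below 10 N of force get their centre of pressure zeroed
(`zero_cop_below`) because CoP is numerically meaningless there. Joint
power is the elementwise moment × velocity product.

**Peaks, events and classification.** Stance is detected from the
vertical ground-reaction force with a 20 N threshold and 25% hysteresis;
push-off is the final 40% of stance (the literature does not pin these
windows; both are parameters). The nine metrics are the peak hip
extension angle, minimum stance knee flexion, peak ankle plantarflexion
angle, the corresponding three moments and three powers, extracted with
the stance/push-off restrictions stated in their names. Crouch severity
maps minimum stance knee flexion to typically developing (< 15°), mild
(15–30°), moderate (30–50°) and severe (> 50°), each boundary belonging
to the higher-severity class; `classification_range()` reports every
class an ensemble's knee range intersects and flags ambiguity when there
is more than one.

## Ensemble generation

**Marker registration.** Each marker's local position is offset
independently by a draw uniform in the closed ball of radius *e*,
realized by rejection from the cube [−e, e]³ (acceptance π/6 per
candidate, so the redraw loop is short and the distribution exactly
uniform — the radius CDF is r³, mean radius 3e/4). An optional per-marker
map of radii supports markers with unequal registration confidence.

**Segment scaling.** Per-segment factors are drawn uniformly from
[0.90, 1.10] (isotropic by default; a per-axis mode exists), the scaled
model is posed by IK against the reference model's calibration-pose
markers, and the set is accepted only if every posed marker lies within
*e* of its original counterpart. Scaling multiplies a segment's com and
marker positions by its own factors and each child's joint centre by the
parent's factors; masses scale with the factor product (volume rule) and
inertias with mass × (stretch along the segment's length axis)², so the
dynamics respond to scaling; `preserve_mass_properties = TRUE` restricts
scaling to geometry. Because IK cannot change distances between markers
on the same segment, candidates whose within-segment pair distances move
by more than 2e are rejected before the IK solve — a strict necessary
condition that leaves the accepted distribution untouched while skipping
most of the expensive checks. At e = 0.5 cm acceptance is roughly 1 in
5000 candidates for the fixture model, which is why the cap
(`rejection_cap`, default 1e5) exists and why its error message suggests
a larger e or a narrower interval.

**Nesting and reproducibility.** Levels are strictly increasing; each
level contributes `n` fresh models and, by default
(`augment_previous = TRUE`), a level's *analysis set* is the union of all
lower levels' models with its own — the ensemble grows by augmentation,
and peak-metric ranges are then weakly monotone in *e* by construction.
The published wording of the generation process supports both this
cumulative reading and fixed-size per-level sets, so
`augment_previous = FALSE` gives independent levels of exactly `n`. Every
(level, draw) pair derives its own RNG sub-stream from the single
configured seed, making ensembles bit-reproducible and independent of
generation order.

**Marker-error metrics.** Ensemble marker errors are measured against the
*original model's* marker positions along its own baseline IK solution —
not against the experimental markers — because the question is whether
the perturbed models stay within the uncertainty margin of the original
solution. The two reported scalars are the RMSE across tracked markers at
each instant, averaged over frames and maximized over models, and the
single maximum marker error over all markers, frames and models.

## The synthetic-gait generator

`generate_trial()` exists so every stage is testable without recorded
data. Joint coordinates follow smooth periodic curves (≤ 3 harmonics per
coordinate) whose amplitudes were fit once to standard gait waypoints:
hip flexion ~30° at heel strike to ~−16° in late stance, knee with a
~19° loading bump, ~6° stance minimum and ~56° swing peak, ankle ~11°
dorsiflexion in late stance and ~−14° plantarflexion around toe-off;
the left leg mirrors the right half a cycle later. Markers come from
forward kinematics plus optional isotropic Gaussian noise (default 0 —
the method isolates model-side uncertainty, and a noise-free fixture
makes the consistency checks exact). External loads are constructed from
the model's own equations of motion: a no-load inverse-dynamics pass
yields the whole-body residual wrench, which is split between the feet by
a smooth cosine weight (60% right-stance duty, 0.12-cycle double-support
ramps) and decomposed per foot into a force, a ground-plane centre of
pressure and a vertical free moment. By construction, feeding the
generated markers and loads back through IK and inverse dynamics
reproduces the stored coordinates to < 1e-6 rad and the stored moments to
< 1e-6 N·m with a numerically zero base residual.

What the generator does **not** emulate: soft-tissue artifact (markers
ride rigidly on segments), force-plate noise and CoP error, marker
occlusions/relabelling, cycle-to-cycle variability, and real GRF
double-support decomposition (the smooth split is a modelling
convenience). Passing tests on this fixture therefore demonstrates the
correctness of the propagation machinery and the qualitative behaviour of
the method — e.g. that ensemble RMSE stays below *e* while peak metrics
spread substantially — not the specific uncertainty magnitudes of any
recorded subject, which depend on the subject-specific model, marker set
and trial.

## Numerical choices and problem sizes

- IK damping starts at 1e-3, shrinks ×3 on success, grows ×10 on
  rejection; normal equations are solved with a diagonal-scaled
  Marquardt term. A stalled step at a flat minimum counts as converged.
- The ball sampler caps its vectorized redraw loop at 1000 rounds purely
  as an internal guard; with acceptance π/6 the cap is unreachable.
- Derived seeds are kept below 2³¹ − 1.
- Text writers use 12 significant digits (TRC/MOT round-trips are exact
  to < 1e-9 in SI units); model YAML uses 15 and round-trips exactly.
- The test suite runs the scaled-down emulation at n = 20 models per
  level for e ∈ {0.5, 1, 2} cm for both strategies on a ~100-frame,
  90 Hz trial; the acceptance script reports n = 10 per level at the
  same levels plus a crouched-trial classification study. These sizes
  were chosen to exercise every code path at interactive runtimes; all
  statistics they compute are defined identically at any n.

## Known limitations

- Joints are idealized (no joint translation with flexion, no axis
  obliquity options beyond the configured axes); only the root may be a
  free joint.
- The filter end effects make the first/last ~0.15 s of derivatives and
  moments unreliable, as in any off-line zero-phase pipeline; peak
  windows in the fixture avoid them, but users analysing events near the
  trial boundary should pad their captures.
- Residual reduction, automated marker registration and soft-tissue
  compensation are out of scope; the base residual is reported, not
  reduced.
- Uncertainty is propagated over marker registration and segment scaling
  only; inertial parameters and joint-axis directions are held fixed.
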